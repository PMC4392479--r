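---
title: "Modeling choices in the Poisson Clicks task: methods and numerical choices"
author: "pclicks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling choices in the Poisson Clicks task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pclicks)
```

## The behavioral model

In the Poisson Clicks task a rat (or a simulated agent) listens to two
simultaneous click trains — left and right speakers, independent Poisson
processes with a summed rate of 40 clicks/s — for an experimenter-controlled
duration of 0.1–1 s, and then reports which side played more clicks. The
package models the decision with a one-dimensional stochastic accumulator
$a(t)$ that integrates right-minus-left click evidence:

$$ da = \sigma_a\, dW + \big(\delta_{t,t_R}\,\eta_R\, C -
        \delta_{t,t_L}\,\eta_L\, C\big)\,dt + \lambda a\, dt, $$

with sticky absorbing bounds: if $|a| \ge B$ then $da/dt = 0$ for the rest
of the trial. Each click is multiplied by a per-click noise $\eta$ and by
the current sensory-adaptation magnitude $C$, which evolves as

$$ \frac{dC}{dt} = \frac{1 - C}{\tau_\phi} +
   (\phi - 1)\, C\,(\delta_{t,t_R} + \delta_{t,t_L}), $$

i.e. immediately after a click $C$ is multiplied by $\phi$
(depression for $\phi < 1$, facilitation for $\phi > 1$) and then relaxes
back to 1 with time constant $\tau_\phi$. The initial condition is
$a(0) \sim N(0, \sigma_i^2)$. At stimulus end the model chooses Right if
$a > \text{sho}$ (the decision boundary), and a lapse fraction of trials is
answered at random. The nine parameters are:

| parameter    | meaning                                   | units     | control value |
|--------------|-------------------------------------------|-----------|--------------|
| `lambda`     | drift rate; $\tau = 1/\lambda$ is the accumulator memory | 1/s | 1.227 |
| `sigma_a2`   | diffusion variance rate                   | u$^2$/s   | 0.001 |
| `sigma_s2`   | multiplicative click-noise variance, per second of the 40/s stimulus | u$^2$/s | 57.614 |
| `sigma_i2`   | initial-value variance                    | u$^2$     | 0.043 |
| `B`          | sticky bound height                       | u         | 16.042 |
| `phi`        | adaptation multiplier                     | –         | 0.221 |
| `tau_phi`    | adaptation recovery time constant         | s         | 0.109 |
| `sho`        | decision boundary                         | u         | 0.065 |
| `lapse`      | random-response fraction                  | –         | 0.102 |

("u" denotes accumulator units; one unadapted, noise-free click moves $a$
by 1.) A unit convention worth spelling out: `sigma_s2` is the click-noise
variance accrued per second of the nominal 40 click/s stimulus, so a click
of adapted amplitude $C$ carries variance $C^2\sigma_s^2/40$
($\eta \sim N(1, \sigma_s^2/40)$). This is the only reading under which the
reference fits reproduce the published behavior: taken as a raw per-click
variance, $\sigma_s^2 = 57.6$ would give each click a noise sd of
$7.6\,C$ and drive easy-trial accuracy toward chance, whereas the
rate-normalized reading yields the observed $\approx 90\%$ asymptote once
the 0.102 lapse is folded in. The control column is the pooled-control
("meta-rat") reference fit
shipped with the package (`meta_rat_params()`), which the synthetic-data
generator uses as its realistic operating point: slightly unstable
accumulation with $\tau \approx 0.8$ s, strong per-click noise, pronounced
depression, and a lapse near 0.1.

Lateralized perturbations are described by a `bias_extension`: reversal
probabilities $\kappa_L, \kappa_R$ applied to already-categorized decisions
(post-categorization bias), per-side click gains, per-side click-noise
variances, and an accumulator shift added before categorization
(equivalent to moving `sho`). The four single-parameter mechanism variants
(`post_cat`, `gain`, `shift`, `noise`) each free one contralateral
parameter with its ipsilateral counterpart held at the control value; the
`eight_param` variant frees $\lambda$, $\sigma_a^2$, both side noises, the
shift, both $\kappa$'s and the contralateral gain, keeping initial noise,
bound and the two adaptation parameters fixed, with the ipsilateral gain
pinned to 1.

## Exact trial likelihoods by density propagation

`propagate_density()` computes the full distribution of $a$ at stimulus end
without path simulation. Because the SDE is linear between clicks, the
inter-click transition kernel is exactly Gaussian with per-bin mean
$a e^{\lambda \Delta t}$ and variance
$\sigma_a^2 (e^{2\lambda\Delta t} - 1) / (2\lambda)$
($\to \sigma_a^2 \Delta t$ as $\lambda \to 0$), and each click contributes
a Gaussian impulse of mean $\pm g C_k$ and variance $g^2 C_k^2 \sigma_s^2$.
The density is therefore propagated event-by-event — only the accumulator
axis is discretized, never time. After every event, mass outside $(-B, B)$
moves to two absorbing bins at $\pm B$ and never returns; checking
absorption once per event is exactly what the Monte-Carlo simulator does,
so the two routes converge to the same trial probabilities.

Numerical choices:

* **Grid.** Uniform bins over $(-B, B)$ with width
  $\min(B/200, 0.05)$ by default, an odd bin count so 0 is a bin center,
  and outer edges exactly at $\pm B$. Halving the bin width changes choice
  probabilities by well under $10^{-3}$ (checked in the test suite).
* **Remap + convolve.** Each event first remaps bin masses to
  $\mu = \text{mult}\cdot x + \text{shift}$ by mean-preserving linear
  interpolation, then convolves with the bin-integrated Gaussian kernel of
  the event sd.
* **Noise-adaptive decimation.** Event kernels can span many grid bins
  (e.g. large per-side noise variances in the perturbation variants, or
  strong diffusion over long inter-click gaps). A Gaussian sampled at a
  pitch of $s/2.5$ is spectrally exact to ~$10^{-9}$, so wide-kernel events
  are convolved on a decimated grid of that pitch: masses are deposited by
  mean-preserving interpolation, convolved, spread back, and smoothed with
  a short boxcar so threshold and bound integrals never see pitch-scale
  steps; all the variance this quantization chain adds (deposit $h^2/6$,
  kernel Sheppard $h^2/12$, upsample $h^2/12$, boxcar $(W^2-1)\,dx^2/12$) is
  subtracted from the kernel width. This bounds the per-event cost
  independently of the noise scale, and the support of the density is
  tracked so empty grid regions cost nothing.
* **Decision boundary.** $P_0(R)$ is the mass strictly above `sho` plus the
  mass absorbed at $+B$; the bin containing `sho` contributes fractionally
  (uniform-within-bin interpolation). Lapse mixing is applied next,
  $P_1 = (1-\text{lapse}) P_0 + \text{lapse}/2$, and the reversals last,
  $P = P_1 (1 - \kappa_R) + (1 - P_1)\kappa_L$. Reversals acting after the
  lapse means they rescale *all* emitted decisions; a consequence worth
  knowing is that on easy trials the ipsi-minus-contra accuracy bias equals
  $\kappa_C$ exactly, and that $\kappa$ and lapse are separately
  identifiable only because the lapse is held at its control value during
  variant fits (the package follows the fixed-control-parameters protocol).
* **Simultaneous left/right clicks** are processed deterministically
  left-then-right and flagged by `adapt_clicks()`; the package does not
  cancel them, but the flag lets a caller implement cancellation.
* **Degenerate inputs.** Zero variances collapse the kernels to pure
  remaps (the noise-free model is reproduced exactly, including the
  ideal-performance limit $a = \#R - \#L$); `lapse = 1` short-circuits to
  $P = 1/2$; a clickless trial is pure drift-diffusion of the initial
  Gaussian.

The dataset log-likelihood is
$\log P(D \mid \theta) = \sum_i \log P(d_i \mid t_{i,R}, t_{i,L}, \theta)$
over accumulation and single-sided trials. A nonzero lapse bounds every
per-trial probability away from zero, so no single trial can dominate a
fit. The batched evaluator can also return each trial's terminal survival
curve, from which any fit that only moves the decision boundary, shift,
lapse or reversal probabilities is re-scored without re-propagating — those
fits cost one propagation pass regardless of the number of likelihood
evaluations.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions: two independent Poisson
click trains with a summed generative rate of 40 clicks/s, stimulus
durations drawn uniformly from 0.1–1 s (the duration schedule is
experimenter-controlled in the task; uniform is the neutral choice and is
config-exposed), and a difficulty ladder of 8 symmetric rate pairs whose
log-ratios are log-spaced from 39:1 down to near-chance, mirrored across
sides so left/right roles are counterbalanced. Trial types are assigned
multinomially — the main-experiment default is 90% accumulation / 10% side
LED; free-choice sessions use 65/25/10; single-sided trials (all clicks on
one side at a fixed 100 clicks/s) make up about 8% of a session where
enabled. The correct side is defined by the realized click counts, with
ties labeled `either` and excluded from accuracy summaries.
`simulate_choices()` draws choices by exact forward simulation of the
accumulator (the same event-driven scheme as the density, with absorption
checked at event times); with many paths per trial it doubles as the
Monte-Carlo oracle the density code is tested against. Clickless trial
types (side LED, free choice) are answered by simple preference
parameters, present only so session bookkeeping can be exercised.
`simulate_unilateral_study()` builds a 30-session perturbation experiment
(128 trials per session, matching the scale of the pooled unilateral
dataset of ~3,800 trials over 30 sessions) with alternating perturbed
sides and a post-categorization reversal of a configurable fraction of
contralateral decisions, then relabels everything into a common ipsi/contra
frame.

What the generator does **not** emulate: fixation violations and aborted
trials, reward and response-time dynamics, inter-trial dependencies
(win-stay/lose-switch), session-to-session drift, and any within-session
drug washout beyond the convention of analyzing only the first 250 trials
of a session. Tests passing on this synthetic data therefore certify the
estimation machinery — not the adequacy of the model for any particular
animal's data.

## Fitting, resampling, sampling, cross-validation

* **Bounds.** $\lambda \in [-40, 40]$, variances in $[0, 500]$ (initial
  variance $[0, 100]$), $B \in [4, 40]$, $\phi \in (0, 2]$,
  $\tau_\phi \in (0, 1]$, `sho` and shift in $[-3, 3]$, $\kappa$ and lapse
  in $[0, 1]$, gains in $[0, 4]$. The lower bound on $B$ keeps the decision
  boundary inside the grid for every admissible `sho`.
* **Single-parameter fits** scan the bound interval densely (default 25
  points; each 1-parameter profile has a single global maximum in
  practice) and polish with Brent's method. Warm-started refits (bootstrap
  resamples, cross-validation folds) instead bracket locally around the
  previous estimate, expand the bracket if the maximum moves, probe inward
  once if it sits on a parameter bound (a boundary optimum such as a zero
  contralateral gain is legitimate), and optionally finish with a single
  parabolic-interpolation step (`refine = "quadratic"`) — three to five
  likelihood evaluations per refit.
* **Multi-parameter fits** use bounded quasi-Newton (`L-BFGS-B`) with
  numeric gradients and 5 multistarts jittered around the control values.
  Analytic gradients are out of scope, matching the original fitting
  strategy for the extended models.
* **Bootstrap** (`bootstrap_fit()`): trials resampled with replacement at
  the original n, 300 refits by default, 95% percentile intervals;
  significance = control value outside the interval.
* **Metropolis–Hastings** (`mh_chains()` / `mh_sample()`): symmetric
  uniform random-walk proposals, per-parameter widths defaulting to 5% of
  the bound range (aiming at the 20–50% acceptance band), 4 chains of
  10,000 samples with burn-in 100 and thinning 4 by default. The machinery
  is validated against a known bivariate Gaussian; a Gelman-style
  split-chain ratio is provided.
* **Leave-one-session-out CV** (`loso_cv()`): for each session, the four
  variants are refit to the remaining sessions (warm-started) and scored
  on the held-out session's log-likelihood per trial; only the first 250
  trials of a session are used.

On identifiability: at the control operating point the 1-parameter profile
over $\lambda$ has a sampling sd of roughly $0.35$ at $n \approx 1200$
trials (from the profile curvature), so drift-rate recovery is good but not
razor-sharp; in noisier, leakier regimes the profile flattens considerably —
consistent with the wide published resampling intervals for $\lambda$ — and
the recovery tests state tolerances from the measured curvature. The
reversal fraction $\kappa_C$ is sharply identified throughout.

## Problem sizes used in the shipped analyses

The analysis scripts and acceptance checks run, on one core, with: 5,000
control trials; 1,809 bilateral-style trials (the published bilateral n);
30 unilateral sessions × 128 trials (≈ the published unilateral n of
3,836); 200 trials × $10^5$ Monte-Carlo paths for the density/simulation
cross-check; bootstrap and posterior-sampling demonstrations at reduced
lengths (60 resamples; 2 × 800 samples). Cross-validation runs on a
0.15-unit likelihood grid — grid error there (≲ $5\times10^{-3}$ in
probability) is far below the ~0.1 log-likelihood-per-trial margin that
separates the winning variant.

## Known limitations

Reaction times and within-trial bound-crossing time distributions are not
modeled; the full 12-parameter simultaneous fit is not attempted (variant
fits follow the fixed-control protocol); adaptation is a single shared
state across both click streams; and the per-click noise is taken as
multiplicative ($\eta C$, variance $C^2\sigma_s^2$) — the alternative
constant-variance reading of the model description is noted but not
implemented.
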