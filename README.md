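# pclicks

Trial-by-trial behavioral modeling for the **Poisson Clicks task**, the
two-alternative auditory evidence-accumulation paradigm used with rats: two
speakers play independent Poisson click trains (summed rate 40 clicks/s)
for 0.1–1 s, and the subject reports which side played more clicks. The
package is for researchers who want to simulate this task, fit the
stochastic accumulator model to choice data click-by-click, and ask which
model parameter a manipulation (e.g. a unilateral cortical inactivation)
has changed.

## The model

A latent accumulator $a(t)$ integrates right-minus-left evidence,

$$ da = \sigma_a\,dW + (\delta_{t,t_R}\,\eta_R\,C - \delta_{t,t_L}\,\eta_L\,C)\,dt + \lambda a\,dt, \qquad |a| \ge B \Rightarrow da/dt = 0 ,$$

with multiplicative per-click noise $\eta$, sensory adaptation
$dC/dt = (1-C)/\tau_\phi + (\phi-1)\,C\,(\delta_{t,t_R}+\delta_{t,t_L})$,
initial condition $a(0) \sim N(0,\sigma_i^2)$, decision
$a > \text{sho} \Rightarrow$ "Right" at stimulus end, and a lapse rate —
nine parameters $(\lambda, \sigma_a^2, \sigma_s^2, \sigma_i^2, B, \phi,
\tau_\phi, \text{sho}, \text{lapse})$. Choice probabilities are computed
*exactly* (to grid tolerance) by propagating the accumulator probability
density between click events with the closed-form linear-SDE kernels, so
the dataset likelihood $P(D\mid\theta) = \prod_i P(d_i \mid t_{i,R},
t_{i,L}, \theta)$ uses every click time of every trial. Lateralized
extensions (post-categorization reversals $\kappa_{L/R}$, side-specific
click gains and noises, an accumulator shift) express competing hypotheses
about what a unilateral perturbation does; information criteria
(BIC/AIC), bootstrap resampling, random-walk Metropolis sampling and
leave-one-session-out cross-validation adjudicate between them. See the
vignette (`vignettes/accumulator-methods.Rmd`) for the numerics.

## Worked example

Simulate a 30-session unilateral-perturbation study in which 50% of
contralateral decisions are reversed after categorization, then ask which
single-parameter mechanism explains the synthetic "infusion" data:

```r
library(pclicks)
th <- meta_rat_params()          # pooled-control reference fit

uni <- simulate_unilateral_study(th, n_sessions = 30,
                                 trials_per_session = 128,
                                 kappa_contra = 0.5, seed = 101)

fits <- lapply(c("post_cat", "gain", "shift", "noise"), function(v)
  fit_mle(uni, make_variant(v, th), grid_dx = 0.1, n_scan = 15))
data.frame(variant = sapply(fits, `[[`, "name"),
           estimate = sapply(fits, function(f) unname(f$par)),
           logLik   = sapply(fits, `[[`, "logLik"))
#>    variant     estimate    logLik
#> 1 post_cat   0.49853834 -1772.679
#> 2     gain   0.03635508 -2156.598
#> 3    shift   3.00000000 -2262.211
#> 4    noise 500.00000000 -2223.581
```

The post-categorization model recovers the injected reversal fraction
(0.499 vs the true 0.5) and beats the next-best mechanism by ~380
log-units; the other mechanisms run to implausible corners of their
ranges trying to mimic the bias. Cross-validation tells the same story
per held-out session:

```r
cv <- loso_cv(uni, th, grid_dx = 0.15, n_scan = 15)
round(attr(cv, "mean"), 3)       # held-out log-likelihood per trial
#> post_cat     gain    shift    noise
#>   -0.462   -0.568   -0.588   -0.579
```

and the behavioral summary matches what such a mechanism looks like in
raw performance — an ipsilateral bias of about the reversal fraction,
independent of trial difficulty:

```r
bs <- bias_summary(uni)
c(mean = attr(bs, "mean"), se = attr(bs, "se"))
#>   mean     se
#> 49.795  1.233   # ipsi - contra % correct across 30 sessions
```

The numbered scripts under `analysis/` run the full pipeline (simulate →
engine checks → fits → model comparison → psychophysics) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_model_checks.R 1
# ...
Rscript analysis/05_psychophysics.R 1
```

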