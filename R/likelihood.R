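#' @useDynLib pclicks, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

default_grid_dx <- function(B) min(B / 200, 0.05)

as_trial <- function(trial) {
  if (is.data.frame(trial)) {
    stopifnot(nrow(trial) == 1L)
    trial <- list(left_clicks = trial$left_clicks[[1L]],
                  right_clicks = trial$right_clicks[[1L]],
                  duration = trial$duration[[1L]])
  }
  stopifnot(is.numeric(trial$duration), trial$duration > 0)
  if (is.null(trial$left_clicks) || is.null(trial$right_clicks))
    stop("trial must carry left_clicks and right_clicks")
  trial
}

# sigma_s2 is expressed as click-noise variance per second of the nominal
# 40 click/s stimulus; each click therefore carries variance C^2 sigma_s2/40.
# (The raw-per-click reading is behaviorally inconsistent with the reference
# fits: it would put easy-trial accuracy near chance.)
click_rate_norm <- 40

# bias with side noises defaulted from the accumulator parameters, still in
# the user-facing (per-second) units
bias_raw <- function(bias, params) {
  if (is.null(bias)) bias <- no_bias()
  list(kappa_L = bias$kappa_L, kappa_R = bias$kappa_R,
       gain_L = bias$gain_L, gain_R = bias$gain_R,
       sigma_s2_L = if (is.null(bias$sigma_s2_L)) params$sigma_s2
                    else bias$sigma_s2_L,
       sigma_s2_R = if (is.null(bias$sigma_s2_R)) params$sigma_s2
                    else bias$sigma_s2_R,
       shift = bias$shift)
}

# as above but with the side noises converted to per-click variances
resolve_bias <- function(bias, params) {
  b <- bias_raw(bias, params)
  b$sigma_s2_L <- b$sigma_s2_L / click_rate_norm
  b$sigma_s2_R <- b$sigma_s2_R / click_rate_norm
  b
}

#' Propagate the accumulator density over one trial
#'
#' Computes the full probability distribution of the accumulator value at
#' stimulus end by event-driven propagation on a uniform grid over
#' \eqn{(-B, B)}: the initial Gaussian \eqn{N(0, \sigma_i^2)} is discretized
#' onto the grid; between consecutive click events the interior density is
#' pushed through the exact linear-SDE transition kernel (per-bin mean
#' \eqn{a e^{\lambda \Delta t}}, variance
#' \eqn{\sigma_a^2 (e^{2\lambda\Delta t} - 1)/(2\lambda)}, with the
#' \eqn{\lambda \to 0} limit \eqn{\sigma_a^2 \Delta t}); each click convolves
#' the density with a Gaussian of mean \eqn{\pm g\, C_k} and variance
#' \eqn{g^2 C_k^2 \sigma_s^2} where \eqn{C_k} is the adapted amplitude and
#' \eqn{g} the side gain. After every event, mass outside \eqn{(-B, B)} is
#' transferred to absorbing bins at \eqn{\pm B} and never returns (sticky
#' bounds). Only the accumulator axis is discretized; time is handled
#' exactly between events.
#'
#' @param trial a one-row trial-set row, or a list with \code{left_clicks},
#'   \code{right_clicks} and \code{duration}.
#' @param params an \code{\link{accum_params}} object.
#' @param bias optional \code{\link{bias_extension}} supplying side gains and
#'   side noises (post-categorization parameters do not affect propagation).
#' @param grid_dx grid bin width; default \code{min(B/200, 0.05)}.
#' @return A \code{density_grid}: list with bin centers \code{x}, interior
#'   \code{mass}, \code{absorbed_lo}/\code{absorbed_hi} bound masses,
#'   \code{dx} and \code{B}.
#' @export
propagate_density <- function(trial, params, bias = NULL, grid_dx = NULL) {
  stopifnot(inherits(params, "accum_params"))
  trial <- as_trial(trial)
  b <- resolve_bias(bias, params)
  if (is.null(grid_dx)) grid_dx <- default_grid_dx(params$B)
  if (grid_dx <= 0 || grid_dx > params$B)
    stop("propagate_density: grid_dx must be in (0, B]")
  ad <- adapt_clicks(trial$left_clicks, trial$right_clicks,
                     params$phi, params$tau_phi)
  g <- cpp_propagate(ad$time, ad$side, ad$amplitude, trial$duration,
                     params$lambda, params$sigma_a2, params$sigma_i2,
                     params$B, grid_dx, b$gain_L, b$gain_R,
                     b$sigma_s2_L, b$sigma_s2_R)
  structure(g, class = "density_grid")
}

# Mass strictly above `sho`; the bin containing sho contributes the fraction
# of its mass lying above sho (uniform-within-bin interpolation).
p_right_from_grid <- function(grid, sho) {
  if (sho < -grid$B || sho > grid$B)
    stop("decision boundary outside [-B, B]")
  x <- grid$x
  dx <- grid$dx
  hi <- x - dx / 2 >= sho            # bins entirely above sho
  p <- grid$absorbed_hi + sum(grid$mass[hi])
  part <- which(!hi & (x + dx / 2) > sho)
  if (length(part))
    p <- p + sum(grid$mass[part] * ((x[part] + dx / 2) - sho) / dx)
  p
}

apply_choice_transforms <- function(p0, lapse, kappa_L, kappa_R) {
  p1 <- (1 - lapse) * p0 + lapse / 2
  p1 * (1 - kappa_R) + (1 - p1) * kappa_L
}

#' Probability of a rightward choice on one trial
#'
#' Propagates the accumulator density (see \code{\link{propagate_density}})
#' and converts the terminal distribution into P(choice = Right):
#' \enumerate{
#'   \item \eqn{P_0} = mass strictly above the decision boundary \code{sho}
#'     (shifted by \code{bias$shift}) plus the mass absorbed at \eqn{+B};
#'   \item lapse mixing, \eqn{P_1 = (1 - \mathrm{lapse}) P_0 + \mathrm{lapse}/2};
#'   \item post-categorization reversals,
#'     \eqn{P = P_1 (1 - \kappa_R) + (1 - P_1) \kappa_L}
#'     (reversals act on all emitted decisions, including lapses).
#' }
#' @inheritParams propagate_density
#' @return P(Right) in [0, 1].
#' @export
choice_probability <- function(trial, params, bias = NULL, grid_dx = NULL) {
  b <- resolve_bias(bias, params)
  if (params$lapse >= 1 && b$kappa_L == b$kappa_R)
    return(apply_choice_transforms(0.5, 1, b$kappa_L, b$kappa_R))
  g <- propagate_density(trial, params, bias, grid_dx)
  p0 <- p_right_from_grid(g, params$sho - b$shift)
  apply_choice_transforms(p0, params$lapse, b$kappa_L, b$kappa_R)
}

ll_trial_types <- c("accumulation", "single_sided")

#' Dataset log-likelihood
#'
#' Sum over trials of \eqn{\log P(\mathrm{choice}_i \mid t_{i,R}, t_{i,L},
#' \theta)}. Only accumulation and single-sided trials enter (other trial
#' types carry no click evidence). A nonzero lapse bounds every per-trial
#' probability away from zero, so no single trial can dominate the fit.
#'
#' @param trials a trial set (see \code{\link{generate_dataset}}) with
#'   recorded choices.
#' @inheritParams propagate_density
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(trials, params, bias = NULL, grid_dx = NULL) {
  trials <- ll_subset(trials)
  ll_eval(build_event_arrays(trials), params, bias, grid_dx)$ll
}

# Concatenated, time-sorted (left before right at ties) event arrays for the
# batched likelihood kernel.
build_event_arrays <- function(trials) {
  n <- nrow(trials)
  times <- vector("list", n)
  sides <- vector("list", n)
  for (i in seq_len(n)) {
    l <- trials$left_clicks[[i]]
    r <- trials$right_clicks[[i]]
    tm <- c(l, r)
    sd <- c(rep(-1L, length(l)), rep(1L, length(r)))
    o <- order(tm, sd)
    times[[i]] <- tm[o]
    sides[[i]] <- sd[o]
  }
  list(times = as.numeric(unlist(times)),
       sides = as.integer(unlist(sides)),
       offsets = c(0L, cumsum(lengths(times))),
       durations = as.numeric(trials$duration),
       went_right = trials$choice == "R",
       n_trials = n)
}

# Batched log-likelihood evaluation; with want_surv = TRUE also returns the
# per-trial terminal survival curves for cheap re-scoring of threshold-type
# parameters.
ll_eval <- function(ev, params, bias = NULL, grid_dx = NULL,
                    want_surv = FALSE) {
  b <- resolve_bias(bias, params)
  if (is.null(grid_dx)) grid_dx <- default_grid_dx(params$B)
  sho_eff <- params$sho - b$shift
  if (sho_eff < -params$B || sho_eff > params$B)
    stop("decision boundary outside [-B, B]")
  cpp_loglik(ev$times, ev$sides, ev$offsets, ev$durations, ev$went_right,
             params$lambda, params$sigma_a2, params$sigma_i2, params$B,
             params$phi, params$tau_phi, sho_eff, params$lapse,
             b$kappa_L, b$kappa_R, grid_dx, b$gain_L, b$gain_R,
             b$sigma_s2_L, b$sigma_s2_R, want_surv)
}

# P0 at an arbitrary decision boundary from stored survival curves
# (columns = trials, rows = bin lower edges from -B to +B).
p0_from_surv <- function(surv, sho, B, dx) {
  n <- nrow(surv) - 1L
  u <- (sho + B) / dx
  j <- max(1L, min(n, floor(u) + 1L))
  w <- u - (j - 1L)
  w <- min(max(w, 0), 1)
  surv[j, ] * (1 - w) + surv[j + 1L, ] * w
}

ll_subset <- function(trials) {
  stopifnot(is.data.frame(trials))
  keep <- trials$trial_type %in% ll_trial_types
  trials <- trials[keep, , drop = FALSE]
  if (nrow(trials) == 0L) stop("log_likelihood: no accumulation/single-sided trials")
  if (any(trials$choice == "none") || anyNA(trials$choice))
    stop("log_likelihood: every included trial needs a recorded choice")
  trials
}

# Terminal densities reusable across values of the post-categorization
# parameters (sho, shift, lapse, kappas): propagate once, re-score cheaply.
terminal_p0 <- function(trials, params, bias = NULL, grid_dx = NULL,
                        sho = params$sho - resolve_bias(bias, params)$shift) {
  vapply(seq_len(nrow(trials)), function(i) {
    g <- propagate_density(trials[i, ], params, bias, grid_dx)
    p_right_from_grid(g, sho)
  }, numeric(1))
}

terminal_grid_list <- function(trials, params, bias = NULL, grid_dx = NULL) {
  lapply(seq_len(nrow(trials)), function(i)
    propagate_density(trials[i, ], params, bias, grid_dx))
}

ll_from_p0 <- function(p0, went_right, lapse, kappa_L, kappa_R) {
  p <- apply_choice_transforms(p0, lapse, kappa_L, kappa_R)
  sum(log(ifelse(went_right, p, 1 - p)))
}
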