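other_side <- function(side) if (side == "R") "L" else "R"

posthoc_param_names <- c("sho", "lapse", "shift", "kappa_ipsi", "kappa_contra")

default_param_bounds <- function() {
  list(lambda = c(-40, 40), sigma_a2 = c(0, 500), sigma_s2 = c(0, 500),
       sigma_i2 = c(0, 100), B = c(4, 40), phi = c(0.001, 2),
       tau_phi = c(0.005, 1), sho = c(-3, 3), lapse = c(0, 1),
       kappa_ipsi = c(0, 1), kappa_contra = c(0, 1),
       gain_ipsi = c(0, 4), gain_contra = c(0, 4),
       sigma_s2_ipsi = c(0, 500), sigma_s2_contra = c(0, 500),
       shift = c(-3, 3))
}

#' General model specification for fitting
#'
#' Describes which parameters are free, their bounds, and the fixed control
#' values. Free parameters are drawn from the nine accumulator parameters
#' plus the lateralized extension parameters (\code{kappa_ipsi},
#' \code{kappa_contra}, \code{gain_contra}, \code{sigma_s2_ipsi},
#' \code{sigma_s2_contra}, \code{shift}); ipsi/contra names are mapped onto
#' physical L/R through \code{ipsi_side}.
#'
#' @param control_params fixed \code{\link{accum_params}} (typically the
#'   control fit).
#' @param free character vector of free parameter names.
#' @param ipsi_side which side is ipsilateral (\code{"R"} after
#'   \code{\link{relabel_ipsi_contra}}).
#' @param bias_control fixed \code{\link{bias_extension}} for the non-free
#'   lateralized parameters (default: unbiased control).
#' @param name label used in comparison tables.
#' @param bounds optional named list overriding default box bounds.
#' @return A \code{model_spec} object.
#' @export
model_spec <- function(control_params, free, ipsi_side = "R",
                       bias_control = NULL, name = NULL, bounds = NULL) {
  stopifnot(inherits(control_params, "accum_params"))
  all_bounds <- default_param_bounds()
  if (!is.null(bounds)) all_bounds[names(bounds)] <- bounds
  bad <- setdiff(free, names(all_bounds))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  if (length(free) == 0L) stop("at least one free parameter required")
  if (is.null(bias_control)) bias_control <- no_bias()
  lower <- vapply(free, function(p) all_bounds[[p]][1], numeric(1))
  upper <- vapply(free, function(p) all_bounds[[p]][2], numeric(1))
  structure(list(control = control_params, free = free,
                 ipsi_side = match.arg(ipsi_side, c("R", "L")),
                 bias_control = bias_control,
                 lower = lower, upper = upper,
                 name = name %||na% paste(free, collapse = "+")),
            class = "model_spec")
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

# Instantiate (params, bias) from a free-parameter vector.
build_model <- function(spec, theta) {
  theta <- as.numeric(theta)
  stopifnot(length(theta) == length(spec$free))
  p <- unclass(spec$control)
  b <- unclass(spec$bias_control)
  ipsi <- spec$ipsi_side
  contra <- other_side(ipsi)
  for (i in seq_along(spec$free)) {
    nm <- spec$free[i]
    v <- theta[i]
    if (nm %in% param_names()) {
      p[[nm]] <- v
    } else if (nm == "shift") {
      b$shift <- v
    } else {
      side <- if (endsWith(nm, "_ipsi")) ipsi else contra
      base <- sub("_(ipsi|contra)$", "", nm)
      b[[paste0(base, "_", side)]] <- v
    }
  }
  list(params = do.call(accum_params, p[param_names()]),
       bias = do.call(bias_extension, b))
}

control_theta <- function(spec) {
  ipsi <- spec$ipsi_side
  contra <- other_side(ipsi)
  p <- unclass(spec$control)
  b <- bias_raw(spec$bias_control, spec$control)
  vapply(spec$free, function(nm) {
    if (nm %in% param_names()) return(p[[nm]])
    if (nm == "shift") return(b$shift)
    side <- if (endsWith(nm, "_ipsi")) ipsi else contra
    b[[paste0(sub("_(ipsi|contra)$", "", nm), "_", side)]]
  }, numeric(1))
}

variant_names <- c("post_cat", "gain", "shift", "noise", "eight_param",
                   "full_9param", "lambda_only", "sho_only")

#' Lateralized bias-model variants
#'
#' Builds the model specifications used to characterize a unilateral
#' perturbation, starting from the best-fitting control parameters:
#' \describe{
#'   \item{post_cat}{post-categorization bias; frees the contralateral
#'     reversal probability \eqn{\kappa_C}, ipsilateral held at 0.}
#'   \item{gain}{unbalanced input gain (sensory neglect); frees the
#'     contralateral click gain, ipsilateral held at 1.}
#'   \item{shift}{accumulator shift added before categorization (equivalent
#'     to moving the decision boundary).}
#'   \item{noise}{unbalanced input noise; frees the contralateral click-noise
#'     variance, ipsilateral held at the control value.}
#'   \item{eight_param}{the extended model freeing \eqn{\lambda},
#'     \eqn{\sigma_a^2}, \eqn{\sigma_{s,I}^2}, shift, \eqn{\kappa_I},
#'     \eqn{\sigma_{s,C}^2}, contralateral gain and \eqn{\kappa_C}; initial
#'     noise, bounds and the two adaptation parameters stay fixed at control,
#'     and the ipsilateral gain is pinned to 1.}
#' }
#' Additionally \code{full_9param}, \code{lambda_only} and \code{sho_only}
#' cover the specifications used for bilateral-perturbation comparisons.
#'
#' @param variant one of \code{post_cat}, \code{gain}, \code{shift},
#'   \code{noise}, \code{eight_param}, \code{full_9param},
#'   \code{lambda_only}, \code{sho_only} (long aliases
#'   \code{post_categorization}, \code{input_gain}, \code{accumulator_shift},
#'   \code{input_noise} accepted).
#' @param control_params control \code{\link{accum_params}}.
#' @param ipsi_side ipsilateral side label (default \code{"R"}, the
#'   convention after \code{\link{relabel_ipsi_contra}}).
#' @return A \code{\link{model_spec}}.
#' @export
make_variant <- function(variant, control_params, ipsi_side = "R") {
  alias <- c(post_categorization = "post_cat", input_gain = "gain",
             accumulator_shift = "shift", input_noise = "noise")
  if (variant %in% names(alias)) variant <- alias[[variant]]
  if (!variant %in% variant_names)
    stop("unknown variant '", variant, "'")
  free <- switch(variant,
    post_cat = "kappa_contra",
    gain = "gain_contra",
    shift = "shift",
    noise = "sigma_s2_contra",
    eight_param = c("lambda", "sigma_a2", "sigma_s2_ipsi", "shift",
                    "kappa_ipsi", "sigma_s2_contra", "gain_contra",
                    "kappa_contra"),
    full_9param = param_names(),
    lambda_only = "lambda",
    sho_only = "sho")
  model_spec(control_params, free, ipsi_side = ipsi_side, name = variant)
}

#' Contra-minus-ipsi bias of a fitted variant
#'
#' The bias induced by a perturbation under a given variant is defined as the
#' best-fitting contralateral parameter minus its ipsilateral counterpart
#' (e.g. \eqn{\kappa_C - \kappa_I}); for the accumulator-shift variant, which
#' has no contra/ipsi pair, the shift itself is returned.
#'
#' @param fit a \code{\link{fit_mle}} result.
#' @return Named scalar bias (for \code{eight_param}, a vector with the
#'   post-categorization and gain biases).
#' @export
variant_bias <- function(fit) {
  spec <- fit$spec
  mdl <- build_model(spec, fit$par)
  b <- bias_raw(mdl$bias, mdl$params)
  ipsi <- spec$ipsi_side
  contra <- other_side(ipsi)
  pair <- function(base) b[[paste0(base, "_", contra)]] -
    b[[paste0(base, "_", ipsi)]]
  switch(spec$name,
    post_cat = c(kappa_bias = pair("kappa")),
    gain = c(gain_bias = pair("gain")),
    noise = c(noise_bias = pair("sigma_s2")),
    shift = c(shift = b$shift),
    eight_param = c(kappa_bias = pair("kappa"), gain_bias = pair("gain"),
                    noise_bias = pair("sigma_s2"), shift = b$shift),
    sho_only = c(sho = mdl$params$sho - spec$control$sho),
    lambda_only = c(lambda = mdl$params$lambda - spec$control$lambda),
    stop("variant_bias: no bias defined for '", spec$name, "'"))
}

mirror_trial_set <- function(trials) {
  out <- trials
  out$left_clicks <- trials$right_clicks
  out$right_clicks <- trials$left_clicks
  out$generative_rate_left <- trials$generative_rate_right
  out$generative_rate_right <- trials$generative_rate_left
  swp <- function(x) ifelse(x == "L", "R", ifelse(x == "R", "L", x))
  out$correct_side <- swp(trials$correct_side)
  out$choice <- swp(trials$choice)
  out
}

#' Relabel left/right trials as ipsi/contra
#'
#' Maps trials from unilateral-perturbation sessions into a common ipsi/contra
#' frame so left- and right-side sessions can be pooled: sessions with a
#' left-side infusion are mirrored (clicks, rates, choices and correct sides
#' swapped) so that after relabeling \code{"R"} always means ipsilateral.
#' Applying the function twice returns the original set.
#'
#' @param trials a trial set whose \code{condition} is \code{left_infusion}
#'   or \code{right_infusion}.
#' @return The relabeled trial set (attribute \code{ipsi_is = "R"}).
#' @export
relabel_ipsi_contra <- function(trials) {
  cond <- unique(trials$condition)
  if (!all(cond %in% c("left_infusion", "right_infusion")))
    stop("relabel_ipsi_contra: condition must specify an infusion side")
  left <- trials$condition == "left_infusion"
  if (any(left)) trials[left, ] <- mirror_trial_set(trials[left, ])
  attr(trials, "ipsi_is") <- "R"
  trials
}
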