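#' Accumulator model parameters
#'
#' Constructs the nine-parameter set of the bounded evidence-accumulation
#' model. The accumulator \eqn{a} integrates right-minus-left click evidence:
#' between clicks \eqn{da = \sigma_a dW + \lambda a\, dt}; a click of adapted
#' amplitude \eqn{C} kicks \eqn{a} by \eqn{\pm\eta C} with
#' \eqn{\eta \sim N(1, \sigma_s^2)}; once \eqn{|a| \ge B} the accumulator
#' freezes (sticky bounds). At stimulus end the model chooses Right when
#' \eqn{a >} \code{sho}, and a lapse fraction of trials is answered at random.
#'
#' @param lambda drift rate (1/s). Negative values give a leaky accumulator
#'   (memory time constant \eqn{\tau = 1/\lambda}), positive an unstable one.
#' @param sigma_a2 diffusion variance rate (units\eqn{^2}/s) of the
#'   accumulator noise.
#' @param sigma_s2 multiplicative click-noise variance, expressed per second
#'   of the nominal 40 click/s stimulus: a click of adapted amplitude C
#'   carries noise variance \eqn{C^2 \sigma_s^2 / 40} (i.e.
#'   \eqn{\eta \sim N(1, \sigma_s^2/40)} multiplies each click). This is the
#'   unit convention of the reference fits; reading the same numbers as raw
#'   per-click variances would put simulated performance near chance.
#' @param sigma_i2 variance of the initial value \eqn{a(0) \sim N(0, \sigma_i^2)}.
#' @param B height of the sticky absorbing bounds (accumulator units, > 0).
#' @param phi sensory adaptation multiplier: immediately after a click the
#'   click magnitude C is multiplied by \code{phi} (\code{phi} < 1 depression,
#'   > 1 facilitation, = 1 none).
#' @param tau_phi recovery time constant (s) with which C relaxes back to 1.
#' @param sho decision boundary compared against \eqn{a} at stimulus end
#'   (choose Right iff \eqn{a >} \code{sho}).
#' @param lapse probability in [0, 1] of a random response.
#' @return An object of class \code{accum_params} (named list).
#' @export
accum_params <- function(lambda = 0, sigma_a2 = 0, sigma_s2 = 0, sigma_i2 = 0,
                         B = 30, phi = 1, tau_phi = 0.1, sho = 0, lapse = 0) {
  p <- list(lambda = lambda, sigma_a2 = sigma_a2, sigma_s2 = sigma_s2,
            sigma_i2 = sigma_i2, B = B, phi = phi, tau_phi = tau_phi,
            sho = sho, lapse = lapse)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("accum_params: '", nm, "' must be a finite numeric scalar")
  }
  if (B <= 0) stop("accum_params: B must be > 0")
  if (tau_phi <= 0) stop("accum_params: tau_phi must be > 0")
  if (phi < 0) stop("accum_params: phi must be >= 0")
  if (lapse < 0 || lapse > 1) stop("accum_params: lapse must be in [0, 1]")
  if (sigma_a2 < 0 || sigma_s2 < 0 || sigma_i2 < 0)
    stop("accum_params: variances must be >= 0")
  structure(p, class = "accum_params")
}

#' @export
print.accum_params <- function(x, ...) {
  cat("Accumulator parameters:\n")
  print(unlist(x))
  invisible(x)
}

param_names <- function() {
  c("lambda", "sigma_a2", "sigma_s2", "sigma_i2", "B", "phi", "tau_phi",
    "sho", "lapse")
}

#' Lateralized bias extension parameters
#'
#' Extension of the accumulator model describing lateralized imperfections
#' used to model unilateral perturbations: post-categorization reversal
#' probabilities \code{kappa_L}/\code{kappa_R} (a fraction of already-made
#' Left/Right decisions is flipped to the other side), per-side click-impact
#' gains, per-side click-noise variances, and a constant \code{shift} added
#' to the accumulator before categorization (equivalent to moving the
#' decision boundary \code{sho}).
#'
#' @param kappa_L,kappa_R probabilities in [0, 1] of reversing a Left / Right
#'   decision.
#' @param gain_L,gain_R click-impact multipliers (control: both 1).
#' @param sigma_s2_L,sigma_s2_R per-side click-noise variances; \code{NULL}
#'   means inherit \code{sigma_s2} from the accumulator parameters.
#' @param shift accumulator units added to \eqn{a} before comparison with
#'   \code{sho}.
#' @param ipsi_side \code{"L"}, \code{"R"} or \code{NA}; which physical side
#'   counts as ipsilateral when translating contra/ipsi labels.
#' @return An object of class \code{bias_extension}.
#' @export
bias_extension <- function(kappa_L = 0, kappa_R = 0, gain_L = 1, gain_R = 1,
                           sigma_s2_L = NULL, sigma_s2_R = NULL, shift = 0,
                           ipsi_side = NA_character_) {
  if (kappa_L < 0 || kappa_L > 1 || kappa_R < 0 || kappa_R > 1)
    stop("bias_extension: kappa values must be in [0, 1]")
  if (gain_L < 0 || gain_R < 0)
    stop("bias_extension: gains must be >= 0")
  if (!is.null(sigma_s2_L) && sigma_s2_L < 0)
    stop("bias_extension: sigma_s2_L must be >= 0")
  if (!is.null(sigma_s2_R) && sigma_s2_R < 0)
    stop("bias_extension: sigma_s2_R must be >= 0")
  structure(list(kappa_L = kappa_L, kappa_R = kappa_R,
                 gain_L = gain_L, gain_R = gain_R,
                 sigma_s2_L = sigma_s2_L, sigma_s2_R = sigma_s2_R,
                 shift = shift, ipsi_side = ipsi_side),
            class = "bias_extension")
}

no_bias <- function() bias_extension()

#' Reference maximum-likelihood parameter sets
#'
#' Published best-fit parameter values for the nine-parameter accumulator
#' model on the Poisson Clicks task, shipped as a plain-text table: one row
#' per subject plus pooled fits ("meta_rat": all control sessions pooled;
#' "bilateral_fof" and "bilateral_ppc": pooled bilateral-inactivation
#' sessions). These are used as realistic generating parameters for synthetic
#' data and as control values for the bias-variant fits.
#'
#' @param which optional row name (e.g. \code{"meta_rat"}); if given, returns
#'   an \code{\link{accum_params}} object for that row.
#' @return A data frame of fits, or a single \code{accum_params}.
#' @export
reference_fits <- function(which = NULL) {
  path <- system.file("extdata", "reference_fits.csv", package = "pclicks")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(which)) return(tab)
  row <- tab[tab$name == which, , drop = FALSE]
  if (nrow(row) != 1L) stop("reference_fits: unknown fit '", which, "'")
  accum_params(lambda = row$lambda, sigma_a2 = row$sigma_a2,
               sigma_s2 = row$sigma_s2, sigma_i2 = row$sigma_i2, B = row$B,
               phi = row$phi, tau_phi = row$tau_phi, sho = row$sho,
               lapse = row$lapse)
}

#' Pooled-control ("meta-rat") accumulator parameters
#'
#' Convenience accessor for the pooled-control reference fit, the canonical
#' realistic parameter regime: slightly unstable accumulation
#' (\eqn{\lambda \approx 1.2}, \eqn{\tau \approx 0.8} s), strong click-noise,
#' pronounced sensory depression (\eqn{\phi \approx 0.22}) and a lapse rate
#' of about 0.1.
#' @return An \code{accum_params} object.
#' @export
meta_rat_params <- function() reference_fits("meta_rat")
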