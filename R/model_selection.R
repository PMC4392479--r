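#' Bayesian information criterion
#'
#' \eqn{BIC = -2 LL + k \ln n} for a model with maximized log-likelihood
#' \eqn{LL}, \eqn{k} free parameters fit to \eqn{n} trials.
#' @param ll maximized log-likelihood.
#' @param k number of free parameters (>= 0).
#' @param n number of data points (>= 1).
#' @return Scalar BIC.
#' @export
bic <- function(ll, k, n) {
  if (any(n < 1)) stop("bic: n must be >= 1")
  if (any(k < 0)) stop("bic: k must be >= 0")
  -2 * ll + k * log(n)
}

#' Akaike information criterion
#'
#' \eqn{AIC = -2 LL + 2 k}; unlike the BIC it does not depend on the number
#' of trials, so it penalizes extra parameters less on large datasets.
#' @inheritParams bic
#' @return Scalar AIC.
#' @export
aic <- function(ll, k) {
  if (any(k < 0)) stop("aic: k must be >= 0")
  -2 * ll + 2 * k
}

#' Information-criterion model comparison table
#'
#' Builds the comparison table for a set of models fit to the same trials:
#' per model the number of free parameters, log-likelihood, BIC and AIC,
#' with the lowest (most likely) BIC and lowest AIC flagged. When the two
#' criteria select different models the disagreement is recorded (it
#' suggests the best model lies between the flagged ones in complexity).
#'
#' @param fits list of \code{\link{fit_mle}} results, or a data frame with
#'   columns \code{name}, \code{k}, \code{ll} (and optionally \code{n}).
#' @param n number of trials (required for a data frame without \code{n};
#'   checked for consistency against fits).
#' @return A \code{model_comparison} data frame with columns \code{model},
#'   \code{k}, \code{ll}, \code{n}, \code{bic}, \code{aic},
#'   \code{best_bic}, \code{best_aic}; attribute \code{agreement} is TRUE
#'   when one model is flagged by both criteria.
#' @export
compare_models <- function(fits, n = NULL) {
  if (is.data.frame(fits)) {
    tab <- data.frame(model = fits$name, k = fits$k, ll = fits$ll)
    tab$n <- if ("n" %in% names(fits)) fits$n else n
  } else {
    tab <- data.frame(
      model = vapply(fits, function(f) f$name, character(1)),
      k = vapply(fits, function(f) f$k, numeric(1)),
      ll = vapply(fits, function(f) f$logLik, numeric(1)),
      n = vapply(fits, function(f) f$n_trials, numeric(1)))
    if (!is.null(n) && any(tab$n != n))
      stop("compare_models: fits disagree with stated n")
  }
  if (is.null(tab$n) || anyNA(tab$n)) stop("compare_models: n required")
  if (length(unique(tab$n)) != 1L)
    stop("compare_models: all models must be fit to the same n trials")
  tab$bic <- bic(tab$ll, tab$k, tab$n)
  tab$aic <- aic(tab$ll, tab$k)
  tab$best_bic <- tab$bic == min(tab$bic)
  tab$best_aic <- tab$aic == min(tab$aic)
  attr(tab, "agreement") <-
    any(tab$best_bic & tab$best_aic)
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  y <- as.data.frame(x)
  y$ll <- round(y$ll, 1)
  y$bic <- round(y$bic, 1)
  y$aic <- round(y$aic, 1)
  y$best_bic <- ifelse(x$best_bic, "*", "")
  y$best_aic <- ifelse(x$best_aic, "+", "")
  print(y, row.names = FALSE)
  if (!attr(x, "agreement"))
    cat("Note: BIC (*) and AIC (+) select different models.\n")
  invisible(x)
}

#' Write a comparison table as delimited text
#' @param x a \code{model_comparison}.
#' @param path output file.
#' @export
write_model_comparison <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("model", "k", "ll", "bic", "aic",
                                        "best_bic", "best_aic")],
                   path, row.names = FALSE)
  invisible(path)
}
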