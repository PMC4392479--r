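#' Four-parameter psychometric sigmoid fit
#'
#' Bins trials by the realized click difference x = #R - #L and fits
#' \deqn{y = y_0 + a / (1 + e^{-(x - x_0)/b})}
#' to the per-bin fraction of rightward choices by weighted nonlinear least
#' squares (weights = trials per bin). \code{y0} is the floor, \code{a + y0}
#' the ceiling, \code{x0} the inflection (clicks) and \code{b} the slope.
#' These fits are descriptive (visualization/summary); the accumulator model
#' is never fit through this curve.
#'
#' @param trials trial set with choices (accumulation/single-sided trials).
#' @return A \code{psychometric_fit}: coefficients, convergence flag, the
#'   binned data, and the fitted function.
#' @export
fit_psychometric <- function(trials) {
  trials <- trials[trials$trial_type %in% ll_trial_types &
                     trials$choice %in% c("L", "R"), , drop = FALSE]
  x <- vapply(seq_len(nrow(trials)), function(i)
    length(trials$right_clicks[[i]]) - length(trials$left_clicks[[i]]),
    numeric(1))
  y <- as.numeric(trials$choice == "R")
  fx <- factor(x, levels = sort(unique(x)))
  dat <- data.frame(x = sort(unique(x)),
                    p = as.numeric(tapply(y, fx, mean)),
                    n = as.integer(table(fx)))
  if (nrow(dat) < 4) stop("fit_psychometric: need >= 4 distinct click bins")

  start <- list(y0 = max(min(dat$p), 0.02),
                a = min(max(dat$p) - min(dat$p), 0.96),
                x0 = stats::weighted.mean(dat$x, dat$n * dat$p * (1 - dat$p)),
                b = max(diff(range(dat$x)) / 8, 0.5))
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ y0 + a / (1 + exp(-(x - x0) / b)), data = dat,
                      start = start, weights = dat$n,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    co <- unlist(start)
    converged <- FALSE
  } else {
    co <- stats::coef(fit)
    converged <- TRUE
  }
  f <- function(x) co[["y0"]] + co[["a"]] / (1 + exp(-(x - co[["x0"]]) / co[["b"]]))
  structure(list(coef = co, converged = converged, data = dat, fun = f),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric sigmoid fit", if (!x$converged) "(NOT converged)", "\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Chronometric curve: accuracy vs stimulus duration by difficulty
#'
#' Trials are split into difficulty terciles of equal size by
#' |log(rate_R / rate_L)| of the generative rates (easy = large imbalance),
#' then binned by stimulus duration within each tercile; accuracy and
#' binomial standard errors are reported per bin. Ties in realized click
#' counts (\code{correct_side == "either"}) are excluded.
#'
#' @param trials trial set with generative rates, durations and choices.
#' @param n_difficulty_bins number of difficulty quantile bins (default 3).
#' @param n_duration_bins number of equal-count duration bins.
#' @return Data frame with difficulty bin, duration bin midpoint, accuracy,
#'   standard error and trial count.
#' @export
chronometric <- function(trials, n_difficulty_bins = 3, n_duration_bins = 4) {
  trials <- trials[trials$trial_type == "accumulation" &
                     trials$choice %in% c("L", "R") &
                     trials$correct_side %in% c("L", "R"), , drop = FALSE]
  if (is.null(trials$generative_rate_left) ||
      anyNA(trials$generative_rate_left))
    stop("chronometric: generative rates required")
  ratio <- abs(log(pmax(trials$generative_rate_right, 1e-9) /
                     pmax(trials$generative_rate_left, 1e-9)))
  # equal-count quantile bins (rank-based so ties split evenly)
  dif <- ceiling(rank(ratio, ties.method = "first") *
                   n_difficulty_bins / length(ratio))
  labs <- if (n_difficulty_bins == 3) c("hard", "medium", "easy")
          else paste0("difficulty_", seq_len(n_difficulty_bins))
  dif <- factor(dif, levels = seq_len(n_difficulty_bins), labels = labs)
  correct <- trials$choice == trials$correct_side
  out <- NULL
  for (d in levels(dif)) {
    ix <- dif == d
    dur <- trials$duration[ix]
    nb <- min(n_duration_bins, length(unique(dur)))
    db <- ceiling(rank(dur, ties.method = "first") * nb / length(dur))
    for (b in seq_len(nb)) {
      jx <- db == b
      p <- mean(correct[ix][jx])
      n <- sum(jx)
      out <- rbind(out, data.frame(
        difficulty = d, duration = mean(dur[jx]), accuracy = p,
        se = sqrt(p * (1 - p) / n), n = n))
    }
  }
  out
}

#' Psychophysical reverse correlation
#'
#' Computes the time course of the excess click rate (right minus left,
#' relative to the generative mean) conditioned on the choice, revealing
#' which part of the stimulus drove decisions. Click trains are binned
#' (default 50 ms) from stimulus onset and truncated at each trial's
#' duration. With \code{model_weights} (per-trial model P(Right)) each trial
#' contributes its predicted probability to the right-choice group and the
#' complement to the left-choice group, yielding the model-predicted kernel.
#'
#' @param trials trial set with click times and choices.
#' @param model_weights optional numeric vector of per-trial P(Right).
#' @param bin_width time bin (s).
#' @return A data frame of class \code{reverse_correlation}: \code{time}
#'   (bin centers), mean excess rate and standard error for the right- and
#'   left-choice groups, and effective trial counts.
#' @export
reverse_correlation <- function(trials, model_weights = NULL,
                                bin_width = 0.05) {
  trials <- trials[trials$trial_type == "accumulation", , drop = FALSE]
  if (nrow(trials) == 0) stop("reverse_correlation: empty trial set")
  if (is.null(model_weights) && any(!trials$choice %in% c("L", "R")))
    stop("reverse_correlation: choices (or model weights) required")
  n <- nrow(trials)
  wR <- if (is.null(model_weights)) as.numeric(trials$choice == "R")
        else model_weights
  if (length(wR) != n) stop("model_weights must match the trial count")
  edges <- seq(0, max(trials$duration), by = bin_width)
  if (edges[length(edges)] < max(trials$duration))
    edges <- c(edges, edges[length(edges)] + bin_width)
  nb <- length(edges) - 1L
  centers <- edges[-1L] - bin_width / 2

  excess <- matrix(NA_real_, n, nb)    # NA past each trial's duration
  for (i in seq_len(n)) {
    nlive <- sum(centers < trials$duration[i])
    if (nlive == 0L) next
    hr <- graphics::hist(trials$right_clicks[[i]], breaks = edges,
                         plot = FALSE)$counts
    hl <- graphics::hist(trials$left_clicks[[i]], breaks = edges,
                         plot = FALSE)$counts
    gen <- trials$generative_rate_right[i] - trials$generative_rate_left[i]
    excess[i, seq_len(nlive)] <- (hr - hl)[seq_len(nlive)] / bin_width - gen
  }
  grp_mean <- function(w) {
    sw <- colSums(w * !is.na(excess), na.rm = TRUE)
    mu <- colSums(w * excess, na.rm = TRUE) / pmax(sw, 1e-12)
    v <- colSums(w * sweep(excess, 2, mu)^2, na.rm = TRUE) / pmax(sw, 1e-12)
    list(mean = mu, se = sqrt(v / pmax(sw, 1)), n = sw)
  }
  r <- grp_mean(matrix(wR, n, nb))
  l <- grp_mean(matrix(1 - wR, n, nb))
  structure(data.frame(time = centers, mean_right = r$mean, se_right = r$se,
                       n_right = r$n, mean_left = l$mean, se_left = l$se,
                       n_left = l$n),
            class = c("reverse_correlation", "data.frame"))
}

#' Per-session ipsi-minus-contra performance bias
#'
#' For trials already relabeled into the ipsi/contra frame (ipsi = "R", see
#' \code{\link{relabel_ipsi_contra}}), computes for each session the
#' ipsilateral percent correct minus contralateral percent correct on
#' accumulation/single-sided trials, and the fraction of ipsilateral choices
#' on free-choice trials. Sessions missing either trial category are dropped
#' with a warning.
#'
#' @param trials relabeled trial set.
#' @return Data frame per session with \code{bias_pct} (ipsi - contra %
#'   correct) and \code{free_ipsi_frac}; attributes \code{mean} and
#'   \code{se} give the across-session summary of the bias.
#' @export
bias_summary <- function(trials) {
  if (!identical(attr(trials, "ipsi_is"), "R"))
    warning("bias_summary: trials not relabeled; assuming ipsi = 'R'")
  out <- NULL
  for (s in unique(trials$session_id)) {
    tr <- trials[trials$session_id == s & trials$choice %in% c("L", "R"), ,
                 drop = FALSE]
    acc <- tr[tr$trial_type %in% ll_trial_types &
                tr$correct_side %in% c("L", "R"), , drop = FALSE]
    ipsi <- acc$correct_side == "R"
    if (!any(ipsi) || !any(!ipsi)) {
      warning("bias_summary: session ", s,
              " lacks ipsi or contra trials; excluded")
      next
    }
    correct <- acc$choice == acc$correct_side
    bias <- 100 * (mean(correct[ipsi]) - mean(correct[!ipsi]))
    fc <- tr$trial_type == "free_choice"
    out <- rbind(out, data.frame(
      session_id = s, bias_pct = bias,
      free_ipsi_frac = if (any(fc)) mean(tr$choice[fc] == "R") else NA_real_,
      n = nrow(acc)))
  }
  if (is.null(out)) stop("bias_summary: no usable sessions")
  attr(out, "mean") <- mean(out$bias_pct)
  attr(out, "se") <- stats::sd(out$bias_pct) / sqrt(nrow(out))
  out
}
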