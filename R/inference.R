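# Objective factory: returns function(theta) -> log-likelihood. When every
# free parameter acts after the accumulator density is formed (decision
# boundary, shift, lapse, reversal probabilities) the trials are propagated
# once and re-scored from their stored terminal survival curves; otherwise
# every evaluation re-propagates.
make_ll_fun <- function(trials, spec, grid_dx = NULL, base = NULL) {
  trials <- ll_subset(trials)
  ev <- build_event_arrays(trials)
  ipsi <- spec$ipsi_side
  # kappa_R flips Right decisions; Right is ipsi when ipsi_side == "R"
  kLname <- if (ipsi == "R") "kappa_contra" else "kappa_ipsi"
  kRname <- if (ipsi == "R") "kappa_ipsi" else "kappa_contra"
  ctrl <- spec$control
  if (all(spec$free %in% posthoc_param_names)) {
    # `base` lets callers share one propagation across several
    # post-categorization fits of the same trials
    if (is.null(base))
      base <- ll_eval(ev, ctrl, spec$bias_control, grid_dx, want_surv = TRUE)
    surv <- base$surv
    dx <- base$dx
    bc <- resolve_bias(spec$bias_control, ctrl)
    idx <- function(nm) match(nm, spec$free)
    function(theta) {
      gv <- function(nm, dflt) if (nm %in% spec$free) theta[idx(nm)] else dflt
      sho <- gv("sho", ctrl$sho) - gv("shift", bc$shift)
      if (sho < -ctrl$B || sho > ctrl$B) return(-Inf)
      p0 <- p0_from_surv(surv, sho, ctrl$B, dx)
      ll_from_p0(p0, ev$went_right, gv("lapse", ctrl$lapse),
                 gv(kLname, bc$kappa_L), gv(kRname, bc$kappa_R))
    }
  } else {
    function(theta) {
      mdl <- build_model(spec, theta)
      res <- tryCatch(ll_eval(ev, mdl$params, mdl$bias, grid_dx),
                      error = function(e) NULL)
      if (is.null(res) || !is.finite(res$ll)) -Inf else res$ll
    }
  }
}

#' Maximum-likelihood fit
#'
#' Maximizes the trial-by-trial choice log-likelihood over the free
#' parameters of a \code{\link{model_spec}}. Single-parameter models are
#' first bracketed by a dense 1-D scan of the bound interval (the fitted
#' 1-parameter models have a single global maximum) and polished with
#' Brent's method; multi-parameter models use bounded quasi-Newton
#' (\code{L-BFGS-B}) with numeric gradients and \code{n_starts} multistarts
#' jittered around the control values. Parameters whose action is purely
#' post-categorization are refit from cached terminal densities, so those
#' fits cost a single propagation pass.
#'
#' @param trials trial set with recorded choices (accumulation and
#'   single-sided trials are used).
#' @param spec a \code{\link{model_spec}} or \code{\link{make_variant}}.
#' @param init optional named start values; for 1-parameter fits a local
#'   bracket around \code{init} replaces the global scan (used to warm-start
#'   resample/cross-validation refits).
#' @param n_starts multistarts for multi-parameter fits.
#' @param n_scan scan points for the 1-D bracket.
#' @param grid_dx likelihood grid pitch (default \code{min(B/200, 0.05)}).
#' @param bracket half-width of the warm-start bracket as a fraction of the
#'   bound range.
#' @return A \code{fit_result}: free-parameter estimates \code{par},
#'   maximized \code{logLik}, \code{k}, \code{n_trials}, instantiated
#'   \code{params}/\code{bias}, convergence flag and evaluation count.
#' @export
fit_mle <- function(trials, spec, init = NULL, n_starts = 5, n_scan = 25,
                    grid_dx = NULL, bracket = 0.1,
                    refine = c("brent", "quadratic"), base = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  refine <- match.arg(refine)
  trials <- ll_subset(trials)
  fun <- make_ll_fun(trials, spec, grid_dx, base = base)
  k <- length(spec$free)
  n_eval <- 0L
  f <- function(th) { n_eval <<- n_eval + 1L; fun(th) }

  if (k == 1L) {
    lo <- spec$lower
    hi <- spec$upper
    if (!is.null(init)) {
      # local bracket around the warm start, expanded toward an edge best;
      # an optimum pinned at a parameter bound is legitimate (e.g. a gain
      # of zero) and is probed once from the inside rather than rescanned
      d <- bracket * (hi - lo)
      xs <- sort(unique(pmin(pmax(c(init - d, init, init + d), lo), hi)))
      vs <- vapply(xs, f, numeric(1))
      b <- which.max(vs)
      tries <- 0L
      while (tries < 4L &&
             ((b == 1L && xs[1] > lo + 1e-12) ||
              (b == length(xs) && xs[length(xs)] < hi - 1e-12))) {
        d <- d * 3
        if (b == 1L) {
          xn <- max(lo, xs[1] - d)
          xs <- c(xn, xs); vs <- c(f(xn), vs)
        } else {
          xn <- min(hi, xs[length(xs)] + d)
          xs <- c(xs, xn); vs <- c(vs, f(xn))
        }
        b <- which.max(vs)
        tries <- tries + 1L
      }
      if (b == 1L || b == length(xs)) {    # best at a bound: probe inside
        nb <- if (b == 1L) xs[2] else xs[length(xs) - 1L]
        xm <- xs[b] + 0.382 * (nb - xs[b])
        vm <- f(xm)
        if (b == 1L) { xs <- append(xs, xm, 1L); vs <- append(vs, vm, 1L) }
        else {
          xs <- append(xs, xm, length(xs) - 1L)
          vs <- append(vs, vm, length(vs) - 1L)
        }
        b <- which.max(vs)
      }
    } else {
      xs <- seq(lo, hi, length.out = n_scan)
      vs <- vapply(xs, f, numeric(1))
      b <- which.max(vs)
    }
    blo <- xs[max(1L, b - 1L)]
    bhi <- xs[min(length(xs), b + 1L)]
    if (b == 1L || b == length(xs)) {
      # boundary optimum; the inside probe above already bracketed it
      opt <- list(maximum = xs[b], objective = vs[b])
      if (refine != "quadratic" && bhi > blo) {
        o2 <- stats::optimize(f, c(blo, bhi), maximum = TRUE,
                              tol = max(1e-6, 1e-3 * (bhi - blo)))
        if (o2$objective > opt$objective) opt <- o2
      }
    } else if (refine == "quadratic") {
      # one-step parabolic interpolation through the bracketing triple
      x1 <- xs[b - 1L]; x2 <- xs[b]; x3 <- xs[b + 1L]
      y1 <- vs[b - 1L]; y2 <- vs[b]; y3 <- vs[b + 1L]
      den <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
      xv <- if (abs(den) > 1e-12)
        x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)) / den
      else x2
      xv <- min(max(xv, blo), bhi)
      yv <- f(xv)
      opt <- if (yv > y2) list(maximum = xv, objective = yv)
             else list(maximum = x2, objective = y2)
    } else {
      opt <- stats::optimize(f, c(blo, bhi), maximum = TRUE,
                             tol = max(1e-6, 1e-3 * (bhi - blo)))
      if (opt$objective < vs[b])
        opt <- list(maximum = xs[b], objective = vs[b])
    }
    par <- stats::setNames(opt$maximum, spec$free)
    ll <- opt$objective
    converged <- TRUE
  } else {
    starts <- list(if (is.null(init)) control_theta(spec) else init)
    if (n_starts > 1L) {
      for (s in seq_len(n_starts - 1L)) {
        jit <- starts[[1L]] +
          stats::runif(k, -0.1, 0.1) * (spec$upper - spec$lower)
        starts[[s + 1L]] <- pmin(pmax(jit, spec$lower), spec$upper)
      }
    }
    best <- NULL
    converged <- FALSE
    for (st in starts) {
      o <- tryCatch(
        stats::optim(pmin(pmax(st, spec$lower), spec$upper),
                     function(th) -f(th), method = "L-BFGS-B",
                     lower = spec$lower, upper = spec$upper,
                     control = list(factr = 1e7, maxit = 200)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value) {
        best <- o
        converged <- o$convergence == 0
      }
    }
    if (is.null(best)) stop("fit_mle: all optimizer starts failed")
    par <- stats::setNames(best$par, spec$free)
    ll <- -best$value
  }
  mdl <- build_model(spec, par)
  structure(list(par = par, logLik = ll, k = k, n_trials = nrow(trials),
                 params = mdl$params, bias = mdl$bias, spec = spec,
                 converged = converged, n_eval = n_eval,
                 name = spec$name),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model '%s': logLik = %.2f (k = %d, n = %d, %s)\n", x$name,
              x$logLik, x$k, x$n_trials,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$par, 4))
  invisible(x)
}

#' Bootstrap confidence intervals by trial resampling
#'
#' Resamples trials with replacement at the original n and refits the model
#' \code{n_boot} times (default 300), warm-starting each refit at the
#' full-data estimate. 95\% percentile confidence intervals are reported; a
#' parameter is flagged significantly different from a reference value when
#' that value falls outside its interval.
#'
#' @inheritParams fit_mle
#' @param n_boot number of resamples.
#' @param seed integer seed for the resampling.
#' @param conf confidence level for the percentile intervals.
#' @return A \code{bootstrap_result}: \code{boot} (n_boot x k matrix of
#'   refit parameters), \code{ll} per resample, \code{ci}, and the full-data
#'   \code{fit}.
#' @export
bootstrap_fit <- function(trials, spec, n_boot = 300, seed = NULL,
                          conf = 0.95, grid_dx = NULL, ...) {
  if (n_boot < 2) stop("bootstrap_fit: n_boot must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  trials <- ll_subset(trials)
  fit0 <- fit_mle(trials, spec, grid_dx = grid_dx, ...)
  n <- nrow(trials)
  k <- length(spec$free)
  boot <- matrix(NA_real_, n_boot, k, dimnames = list(NULL, spec$free))
  ll <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    res <- trials[sample.int(n, n, replace = TRUE), , drop = FALSE]
    fb <- fit_mle(res, spec, init = fit0$par, n_starts = 1,
                  grid_dx = grid_dx, ...)
    boot[b, ] <- fb$par
    ll[b] <- fb$logLik
  }
  alpha <- (1 - conf) / 2
  ci <- t(apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(boot = boot, ll = ll, ci = ci, conf = conf, fit = fit0,
                 n_boot = n_boot, seed = seed),
            class = "bootstrap_result")
}

#' Is a reference value outside the bootstrap interval?
#' @param x a \code{bootstrap_result}.
#' @param ref named reference values (e.g. the control fit).
#' @return Logical vector per parameter.
#' @export
ci_excludes <- function(x, ref) {
  stopifnot(inherits(x, "bootstrap_result"))
  ref <- ref[rownames(x$ci)]
  unlist(ref) < x$ci[, "lower"] | unlist(ref) > x$ci[, "upper"]
}

#' Random-walk Metropolis sampler
#'
#' Symmetric uniform random-walk Metropolis over an arbitrary log-density:
#' proposals add independent Uniform(-w, w) perturbations per coordinate.
#' Runs \code{n_chains} independent chains, drops \code{burnin} initial
#' samples and keeps every \code{thin}-th thereafter. The same machinery
#' drives the model posterior sampler \code{\link{mh_sample}} and can be
#' pointed at a known density to validate the sampler itself.
#'
#' @param logpost function(theta) -> log density (up to a constant).
#' @param init numeric start vector.
#' @param widths per-coordinate proposal half-widths (> 0).
#' @param lower,upper box constraints (density is -Inf outside).
#' @param n_chains,n_samples,burnin,thin chain geometry; retained samples per
#'   chain = floor((n_samples - burnin)/thin).
#' @param seed integer seed.
#' @return A \code{chain_set}: list of per-chain matrices, acceptance rates,
#'   widths and geometry. Acceptance outside [0.05, 0.8] triggers a warning.
#' @export
mh_chains <- function(logpost, init, widths, lower = -Inf, upper = Inf,
                      n_chains = 4, n_samples = 10000, burnin = 100,
                      thin = 4, seed = NULL) {
  if (any(widths <= 0)) stop("mh_chains: proposal widths must be positive")
  if (!is.null(seed)) set.seed(seed)
  k <- length(init)
  lower <- rep_len(lower, k)
  upper <- rep_len(upper, k)
  keep <- seq(burnin + thin, n_samples, by = thin)
  chains <- vector("list", n_chains)
  acc <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    x <- init
    lp <- logpost(x)
    if (!is.finite(lp)) stop("mh_chains: init has non-finite log density")
    out <- matrix(NA_real_, length(keep), k,
                  dimnames = list(NULL, names(init)))
    nacc <- 0L
    row <- 1L
    for (s in seq_len(n_samples)) {
      prop <- x + stats::runif(k, -widths, widths)
      lpp <- if (any(prop < lower | prop > upper)) -Inf else logpost(prop)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        x <- prop
        lp <- lpp
        nacc <- nacc + 1L
      }
      if (row <= length(keep) && s == keep[row]) {
        out[row, ] <- x
        row <- row + 1L
      }
    }
    chains[[ch]] <- out
    acc[ch] <- nacc / n_samples
  }
  if (any(acc < 0.05 | acc > 0.8))
    warning(sprintf("MH acceptance rate outside [0.05, 0.8]: %s",
                    paste(sprintf("%.2f", acc), collapse = ", ")))
  structure(list(chains = chains, acceptance = acc, widths = widths,
                 n_samples = n_samples, burnin = burnin, thin = thin,
                 seed = seed),
            class = "chain_set")
}

#' Posterior samples for a model specification
#'
#' Runs \code{\link{mh_chains}} on the trial log-likelihood (flat prior over
#' the box bounds), starting at the control values. Default proposal
#' half-widths are 5\% of each parameter's bound range.
#'
#' @inheritParams fit_mle
#' @inheritParams mh_chains
#' @param proposal_widths optional named per-parameter widths.
#' @return A \code{chain_set} with an extra \code{pars} attribute naming the
#'   sampled parameters.
#' @export
mh_sample <- function(trials, spec, n_chains = 4, n_samples = 10000,
                      burnin = 100, thin = 4, proposal_widths = NULL,
                      seed = NULL, grid_dx = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  fun <- make_ll_fun(ll_subset(trials), spec, grid_dx)
  init <- stats::setNames(control_theta(spec), spec$free)
  if (is.null(proposal_widths))
    proposal_widths <- 0.05 * (spec$upper - spec$lower)
  cs <- mh_chains(fun, init, proposal_widths, spec$lower, spec$upper,
                  n_chains, n_samples, burnin, thin, seed)
  attr(cs, "pars") <- spec$free
  cs
}

#' Split-chain convergence ratio (Gelman-style R-hat)
#' @param x a \code{chain_set}.
#' @return Named vector of potential-scale-reduction ratios per parameter.
#' @export
gelman_ratio <- function(x) {
  stopifnot(inherits(x, "chain_set"))
  mats <- x$chains
  k <- ncol(mats[[1]])
  nm <- colnames(mats[[1]])
  out <- vapply(seq_len(k), function(j) {
    draws <- lapply(mats, function(m) m[, j])
    n <- min(lengths(draws))
    draws <- lapply(draws, function(d) d[seq_len(n)])
    mns <- vapply(draws, mean, numeric(1))
    vrs <- vapply(draws, stats::var, numeric(1))
    W <- mean(vrs)
    Bv <- n * stats::var(mns)
    sqrt(((n - 1) / n * W + Bv / n) / W)
  }, numeric(1))
  stats::setNames(out, nm)
}

#' Normalized likelihood surface over two parameters
#'
#' Evaluates the dataset log-likelihood on a 2-D grid with every other
#' parameter fixed at its control value, and normalizes the likelihood to a
#' maximum of 1. When one axis is a post-categorization parameter the trials
#' are propagated only once per value of the other axis.
#'
#' @inheritParams fit_mle
#' @param param_x,param_y free-parameter names (see \code{\link{model_spec}}).
#' @param grid_x,grid_y numeric grids.
#' @return A \code{likelihood_surface}: \code{x}, \code{y}, matrix \code{ll}
#'   and normalized \code{z} (rows follow \code{grid_x}).
#' @export
likelihood_surface <- function(trials, control_params, param_x, param_y,
                               grid_x, grid_y, ipsi_side = "R",
                               bias_control = NULL, grid_dx = NULL) {
  stopifnot(all(is.finite(grid_x)), all(is.finite(grid_y)))
  trials <- ll_subset(trials)
  swap <- param_x %in% posthoc_param_names &&
    !(param_y %in% posthoc_param_names)
  px <- if (swap) param_y else param_x
  py <- if (swap) param_x else param_y
  gx <- if (swap) grid_y else grid_x
  gy <- if (swap) grid_x else grid_y

  spec2 <- model_spec(control_params, c(px, py), ipsi_side = ipsi_side,
                      bias_control = bias_control)
  ll <- matrix(NA_real_, length(gx), length(gy))
  if (py %in% posthoc_param_names) {
    for (ix in seq_along(gx)) {
      mdl <- build_model(spec2, c(gx[ix], control_theta(spec2)[2]))
      spec_y <- model_spec(mdl$params, py, ipsi_side = ipsi_side,
                           bias_control = mdl$bias)
      fy <- make_ll_fun(trials, spec_y, grid_dx)
      ll[ix, ] <- vapply(gy, fy, numeric(1))
    }
  } else {
    f2 <- make_ll_fun(trials, spec2, grid_dx)
    for (ix in seq_along(gx))
      ll[ix, ] <- vapply(gy, function(y) f2(c(gx[ix], y)), numeric(1))
  }
  if (swap) ll <- t(ll)
  structure(list(x = grid_x, y = grid_y, ll = ll,
                 z = exp(ll - max(ll, na.rm = TRUE)),
                 param_x = param_x, param_y = param_y),
            class = "likelihood_surface")
}

#' Leave-one-session-out cross-validation of the bias variants
#'
#' For each session, fits each model variant to all other sessions (warm
#' started at the full-data fit) and evaluates the held-out session's
#' log-likelihood per trial. Only the first \code{max_trials_per_session}
#' trials of each session are used.
#'
#' @param trials trial set with a \code{session_id} column (>= 2 sessions).
#' @param control_params control parameters the variants start from.
#' @param variants character vector of \code{\link{make_variant}} names.
#' @inheritParams fit_mle
#' @param max_trials_per_session per-session trial cap.
#' @return Matrix (sessions x variants) of held-out log-likelihood per
#'   trial, with attribute \code{mean} (column means) and \code{fits} (the
#'   full-data fits).
#' @export
loso_cv <- function(trials, control_params,
                    variants = c("post_cat", "gain", "shift", "noise"),
                    ipsi_side = "R", grid_dx = NULL,
                    max_trials_per_session = 250, n_scan = 25,
                    refine = "quadratic") {
  trials <- ll_subset(trials)
  trials <- truncate_sessions(trials, max_trials_per_session)
  sess <- unique(trials$session_id)
  if (length(sess) < 2) stop("loso_cv: need at least 2 sessions")
  specs <- lapply(variants, make_variant, control_params = control_params,
                  ipsi_side = ipsi_side)
  posthoc <- vapply(specs, function(sp)
    all(sp$free %in% posthoc_param_names), logical(1))
  shared_base <- function(tr) {
    if (!any(posthoc)) return(NULL)
    ll_eval(build_event_arrays(tr), control_params, no_bias(), grid_dx,
            want_surv = TRUE)
  }
  full_base <- shared_base(trials)
  full_fits <- lapply(seq_along(specs), function(vi)
    fit_mle(trials, specs[[vi]], grid_dx = grid_dx, n_scan = n_scan,
            refine = refine, base = if (posthoc[vi]) full_base else NULL))
  out <- matrix(NA_real_, length(sess), length(variants),
                dimnames = list(sess, variants))
  for (si in seq_along(sess)) {
    held <- trials$session_id == sess[si]
    train <- trials[!held, , drop = FALSE]
    test <- trials[held, , drop = FALSE]
    train_base <- shared_base(train)
    test_base <- shared_base(test)
    for (vi in seq_along(variants)) {
      b_tr <- if (posthoc[vi]) train_base else NULL
      b_te <- if (posthoc[vi]) test_base else NULL
      fit <- fit_mle(train, specs[[vi]], init = full_fits[[vi]]$par,
                     n_starts = 1, grid_dx = grid_dx, n_scan = n_scan,
                     refine = refine, base = b_tr)
      ftest <- make_ll_fun(test, specs[[vi]], grid_dx, base = b_te)
      out[si, vi] <- ftest(fit$par) / nrow(test)
    }
  }
  structure(out, mean = colMeans(out), fits = full_fits, class = "loso_result")
}

#' Keep only the first n trials of every session
#' @param trials trial set.
#' @param n per-session cap (default 250, matching the practice of analyzing
#'   only the early, pharmacologically stable part of a session).
#' @return Truncated trial set.
#' @export
truncate_sessions <- function(trials, n = 250) {
  keep <- unlist(lapply(split(seq_len(nrow(trials)), trials$session_id),
                        function(ix) ix[seq_len(min(length(ix), n))]))
  trials[sort(keep), , drop = FALSE]
}
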