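# Descriptive analyses: psychometric sigmoid, chronometric curves,
# reverse correlation and bias summaries.

th_meta <- meta_rat_params()

test_that("the 4-parameter sigmoid is recovered from binomial data", {
  set.seed(61)
  truth <- c(y0 = 0.05, a = 0.9, x0 = 0, b = 3)
  x <- sample(-15:15, 10000, replace = TRUE)
  p <- truth["y0"] + truth["a"] / (1 + exp(-(x - truth["x0"]) / truth["b"]))
  went_r <- runif(10000) < p
  nl <- ifelse(x < 0, -x, 0) + 5
  nr <- ifelse(x > 0, x, 0) + 5
  ds <- trials_from_counts(nl, nr, choice = ifelse(went_r, "R", "L"))
  fit <- fit_psychometric(ds)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[["y0"]] - 0.05), 0.05)
  expect_lt(abs(fit$coef[["a"]] - 0.9), 0.18)       # within 20%
  expect_lt(abs(fit$coef[["x0"]] - 0), 1)
  expect_lt(abs(fit$coef[["b"]] - 3), 0.6)
  # fitted curve stays in [0, 1] and is monotone for a, b > 0
  xs <- seq(-15, 15, by = 0.5)
  expect_true(all(fit$fun(xs) >= 0 & fit$fun(xs) <= 1))
  expect_true(all(diff(fit$fun(xs)) > 0))
})

test_that("stimulus-independent choices give a flat psychometric curve", {
  set.seed(62)
  x <- sample(-12:12, 4000, replace = TRUE)
  ds <- trials_from_counts(ifelse(x < 0, -x, 0) + 4,
                           ifelse(x > 0, x, 0) + 4,
                           choice = sample(c("L", "R"), 4000, TRUE))
  fit <- fit_psychometric(ds)
  expect_lt(abs(fit$coef[["a"]]), 0.2)   # flat up to binomial noise-chasing
})

test_that("post-categorization bias vertically rescales the curve", {
  set.seed(63)
  ds <- generate_dataset(6000, mixture = c(accumulation = 1))
  ctrl <- simulate_choices(ds, th_meta, seed = 64)
  pert <- simulate_choices(ds, th_meta, seed = 64,
                           bias = bias_extension(kappa_L = 0.4))
  f0 <- fit_psychometric(ctrl)
  f1 <- fit_psychometric(pert)
  expect_lt(f1$coef[["a"]], f0$coef[["a"]] - 0.2)   # compressed range
  expect_lt(abs(f1$coef[["x0"]] - f0$coef[["x0"]]), 2.5)
})

test_that("chronometric terciles are equal-count partitions and accuracy
           grows with duration for a perfect integrator", {
  set.seed(65)
  ds <- generate_dataset(6000, mixture = c(accumulation = 1))
  ds <- simulate_choices(ds, ideal_params())
  ch <- chronometric(ds, n_duration_bins = 4)
  counts <- tapply(ch$n, ch$difficulty, sum)
  expect_lte(diff(range(counts)), 3)   # equal tercile sizes (tie handling)
  expect_equal(sum(ch$n),
               sum(ds$correct_side %in% c("L", "R") &
                     ds$choice %in% c("L", "R")))
  for (d in unique(ch$difficulty)) {
    acc <- ch$accuracy[ch$difficulty == d]
    expect_true(all(diff(acc) > -0.03))   # non-decreasing up to noise
  }
  # no trial is counted in two difficulty bins
  expect_equal(anyDuplicated(interaction(ch$difficulty, ch$duration)), 0)
})

test_that("a single duration value collapses to one duration bin", {
  set.seed(66)
  ds <- generate_dataset(300, mixture = c(accumulation = 1),
                         duration_range = c(0.5, 0.5))
  ds <- simulate_choices(ds, th_meta)
  ch <- chronometric(ds)
  expect_equal(nrow(ch), 3)
  expect_setequal(ch$difficulty, c("hard", "medium", "easy"))
})

test_that("model-weighted reverse correlation splits trials by P(Right)", {
  ds <- trials_from_counts(4, 6, duration = 0.2)
  ds$choice <- "R"
  rc <- reverse_correlation(ds, model_weights = 0.67, bin_width = 0.05)
  expect_equal(rc$n_right, rep(0.67, nrow(rc)))
  expect_equal(rc$n_left, rep(0.33, nrow(rc)))
})

test_that("reverse correlation is flat for a perfect integrator and shows
           recency for a leaky one", {
  set.seed(67)
  ds <- generate_dataset(5000, mixture = c(accumulation = 1),
                         duration_range = c(0.5, 0.5))
  p_flat <- accum_params(lambda = 0, sigma_s2 = 9, sigma_i2 = 1, B = 100,
                         phi = 1, tau_phi = 0.1)
  sep_slope <- function(trials) {
    rc <- reverse_correlation(trials)
    sep <- rc$mean_right - rc$mean_left
    se <- sqrt(rc$se_right^2 + rc$se_left^2)
    fit <- lm(sep ~ rc$time, weights = 1 / se^2)
    summary(fit)$coefficients[2, c(1, 3)]   # slope and its t-value
  }
  flat <- sep_slope(simulate_choices(ds, p_flat))
  leaky <- sep_slope(simulate_choices(ds, with_params(p_flat, lambda = -4)))
  expect_lt(abs(flat[2]), 4)       # no time dependence beyond noise
  expect_gt(leaky[2], 4)           # separation grows toward stimulus end
  expect_gt(leaky[1], flat[1])
})

test_that("reverse correlation mirrors under stimulus relabeling", {
  set.seed(68)
  ds <- generate_dataset(400, mixture = c(accumulation = 1),
                         duration_range = c(0.5, 0.5))
  ds <- simulate_choices(ds, th_meta)
  rc <- reverse_correlation(ds)
  mir <- pclicks:::mirror_trial_set(ds)
  rcm <- reverse_correlation(mir)
  expect_equal(rc$mean_right, -rcm$mean_left, tolerance = 1e-9)
  expect_equal(rc$mean_left, -rcm$mean_right, tolerance = 1e-9)
})

test_that("session bias is ipsi minus contra percent correct", {
  # constructed sessions with known outcomes
  ds <- trials_from_counts(c(2, 10, 10, 2), c(10, 2, 2, 10))
  ds$choice <- c("R", "L", "L", "R")        # all correct
  attr(ds, "ipsi_is") <- "R"
  bs <- bias_summary(ds)
  expect_equal(bs$bias_pct, 0)
  ds$choice <- c("R", "R", "R", "R")        # ipsi always, contra never
  bs2 <- bias_summary(ds)
  expect_equal(bs2$bias_pct, 100)
})

test_that("kappa-generated bias equals the injected reversal fraction", {
  # with reversals composed after the lapse, easy-trial bias is kappa_C:
  # ipsi %correct = (1 - l/2) + (l/2) k, contra %correct = (1 - l/2)(1 - k)
  # + ... algebra collapses to bias = 100 k, verified here by simulation
  set.seed(69)
  uni <- simulate_unilateral_study(with_params(th_meta, lapse = 0.1),
                                   n_sessions = 8,
                                   trials_per_session = 250,
                                   kappa_contra = 0.5, seed = 70)
  # restrict to very easy trials so the accumulator is almost always right
  uni <- uni[abs(lengths(uni$right_clicks) - lengths(uni$left_clicks)) > 8, ]
  bs <- bias_summary(uni)
  expect_lt(abs(attr(bs, "mean") - 50), 6)
})
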