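# Fitting, bootstrap, Metropolis-Hastings machinery and surfaces.

th_meta <- meta_rat_params()

test_that("post-categorization kappa is recovered from synthetic data", {
  set.seed(41)
  ds <- generate_dataset(2000, mixture = c(accumulation = 1),
                         condition = "right_infusion")
  ds <- simulate_choices(ds, th_meta,
                         bias = bias_extension(kappa_L = 0.5))
  fit <- fit_mle(ds, make_variant("post_cat", th_meta))
  expect_lt(abs(fit$par - 0.5), 0.05)
  expect_true(fit$converged)
  expect_equal(fit$k, 1)
})

test_that("the drift rate is recovered to within its sampling spread", {
  # profile curvature at the control point gives a sampling sd of ~0.35 for
  # the 1-parameter drift fit at this n; the tolerance is ~4 of those
  set.seed(42)
  ds <- generate_dataset(1200, mixture = c(accumulation = 1))
  ds <- simulate_choices(ds, th_meta)
  fit <- fit_mle(ds, make_variant("lambda_only", th_meta), n_scan = 17,
                 grid_dx = 0.1)
  expect_lt(abs(fit$par - th_meta$lambda), 1.5)
  # the fitted value must beat the generating value in likelihood
  fun <- pclicks:::make_ll_fun(ds, make_variant("lambda_only", th_meta),
                               grid_dx = 0.1)
  expect_gte(fun(fit$par), fun(th_meta$lambda) - 1e-6)
})

test_that("coin-flip data pins the likelihood at its ceiling", {
  set.seed(43)
  ds <- generate_dataset(150, mixture = c(accumulation = 1))
  ds <- simulate_choices(ds, with_params(th_meta, lapse = 1))
  # lapse free, everything else at control: the ceiling is n*ln(1/2)
  fit <- fit_mle(ds, model_spec(th_meta, "lapse"), grid_dx = 0.2)
  expect_lt(abs(fit$logLik - 150 * log(0.5)), 1)
})

test_that("bootstrap defaults, degenerate data and serialization", {
  expect_equal(formals(bootstrap_fit)$n_boot, 300)
  # a dataset of one repeated trial resamples to itself: zero-width CIs
  tr <- generate_trial(5, 35, 0.5, seed = 44)
  tr <- simulate_choices(tr, th_meta, seed = 45)
  rep40 <- tr[rep(1, 40), ]
  rep40$trial_id <- 1:40
  bs <- bootstrap_fit(rep40, make_variant("post_cat", th_meta),
                      n_boot = 12, seed = 46, grid_dx = 0.2)
  expect_equal(unname(bs$ci[, "upper"] - bs$ci[, "lower"]), 0,
               tolerance = 1e-8)
  expect_equal(nrow(bs$boot), 12)
  expect_true(all(bs$ci[, "lower"] <= bs$ci[, "upper"]))
  path <- tempfile(fileext = ".csv")
  write_bootstrap_result(bs, path)
  re <- read.csv(path, comment.char = "#")
  expect_equal(nrow(re), 12)
  expect_true(all(c("kappa_contra", "ll") %in% names(re)))
  expect_error(bootstrap_fit(rep40, make_variant("post_cat", th_meta),
                             n_boot = 1), "n_boot")
})

test_that("bootstrap intervals cover the generating parameter", {
  # scaled-down coverage study on the strongly identified reversal fraction
  set.seed(47)
  cover <- logical(12)
  for (r in seq_along(cover)) {
    ds <- generate_dataset(250, mixture = c(accumulation = 1),
                           condition = "right_infusion")
    ds <- simulate_choices(ds, th_meta, bias = bias_extension(kappa_L = 0.4))
    bs <- bootstrap_fit(ds, make_variant("post_cat", th_meta), n_boot = 50,
                        grid_dx = 0.2)
    cover[r] <- bs$ci[1, "lower"] <= 0.4 && 0.4 <= bs$ci[1, "upper"]
  }
  expect_gte(sum(cover), 9)   # nominal 95%; small-replicate slack
})

test_that("MH machinery recovers a known bivariate Gaussian", {
  mu <- c(1, -2)
  S <- matrix(c(1, 0.6, 0.6, 2), 2)
  Si <- solve(S)
  logpost <- function(x) -0.5 * drop(t(x - mu) %*% Si %*% (x - mu))
  cs <- mh_chains(logpost, init = c(0, 0), widths = c(1.5, 2),
                  n_chains = 4, n_samples = 10000, burnin = 100, thin = 4,
                  seed = 48)
  expect_length(cs$chains, 4)
  expect_equal(nrow(cs$chains[[1]]), 2475)   # (10000 - 100) / 4
  draws <- do.call(rbind, cs$chains)
  n_eff <- nrow(draws) / 10                  # conservative correlation factor
  for (j in 1:2) {
    se <- sqrt(S[j, j] / n_eff)
    expect_lt(abs(mean(draws[, j]) - mu[j]), 3 * se)
  }
  expect_lt(abs(cov(draws)[1, 2] - 0.6), 0.3)
  expect_true(all(cs$acceptance > 0.05 & cs$acceptance < 0.8))
  expect_true(all(gelman_ratio(cs) < 1.1))
  expect_error(mh_chains(logpost, c(0, 0), widths = c(0, 1)), "widths")
})

test_that("model posterior sampling runs through the same machinery", {
  set.seed(49)
  ds <- generate_dataset(60, mixture = c(accumulation = 1),
                         condition = "right_infusion")
  ds <- simulate_choices(ds, th_meta, bias = bias_extension(kappa_L = 0.5))
  sp <- make_variant("post_cat", th_meta)
  cs <- mh_sample(ds, sp, n_chains = 2, n_samples = 400, burnin = 40,
                  thin = 4, seed = 50, grid_dx = 0.2,
                  proposal_widths = 0.2)
  expect_equal(nrow(cs$chains[[1]]), 90)
  draws <- do.call(rbind, cs$chains)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_gt(mean(draws), 0.2)    # mass concentrates near the true reversal
})

test_that("likelihood surfaces normalize to 1 and agree with the MLE", {
  set.seed(51)
  ds <- generate_dataset(250, mixture = c(accumulation = 1))
  ds <- simulate_choices(ds, with_params(th_meta, lambda = -3))
  gl <- seq(-8, 2, length.out = 9)
  gp <- seq(0, 0.5, length.out = 9)
  sf <- likelihood_surface(ds, th_meta, "lambda", "lapse", gl, gp,
                           grid_dx = 0.2)
  expect_equal(max(sf$z), 1)
  expect_equal(dim(sf$ll), c(9, 9))
  amax <- arrayInd(which.max(sf$ll), dim(sf$ll))
  fit2 <- fit_mle(ds, model_spec(th_meta, c("lambda", "lapse")),
                  n_starts = 2, grid_dx = 0.2)
  # agreement within one grid cell on each axis
  expect_lte(abs(gl[amax[1]] - fit2$par[["lambda"]]), diff(gl)[1] + 1e-9)
  expect_lte(abs(gp[amax[2]] - fit2$par[["lapse"]]), diff(gp)[1] + 1e-9)
  # surfaces are invariant to trial order
  sf2 <- likelihood_surface(ds[sample(nrow(ds)), ], th_meta, "lambda",
                            "lapse", gl, gp, grid_dx = 0.2)
  expect_equal(sf$ll, sf2$ll, tolerance = 1e-9)
})

test_that("cross-validation input checking and session truncation", {
  set.seed(52)
  ds <- generate_dataset(30, mixture = c(accumulation = 1))
  ds <- simulate_choices(ds, th_meta)
  expect_error(loso_cv(ds, th_meta), "2 sessions")
  tr <- truncate_sessions(ds, 10)
  expect_equal(nrow(tr), 10)
  expect_equal(tr$trial_id, 1:10)
})
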