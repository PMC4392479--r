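# Density propagation, choice probabilities and the dataset likelihood.

th_meta <- meta_rat_params()

test_that("interior plus absorbed mass is conserved at 1e-6", {
  set.seed(21)
  for (rep in 1:8) {
    p <- accum_params(lambda = runif(1, -5, 5), sigma_a2 = runif(1, 0, 50),
                      sigma_s2 = runif(1, 0, 100), sigma_i2 = runif(1, 0, 2),
                      B = runif(1, 5, 25), phi = runif(1, 0.05, 1.5),
                      tau_phi = runif(1, 0.02, 0.5), sho = runif(1, -1, 1),
                      lapse = runif(1, 0, 0.3))
    tr <- generate_trial(runif(1, 1, 39), runif(1, 1, 39),
                         runif(1, 0.1, 1))
    g <- propagate_density(tr, p)
    expect_lt(abs(sum(g$mass) + g$absorbed_lo + g$absorbed_hi - 1), 1e-6)
    expect_true(all(g$mass >= 0))
  }
})

test_that("halving the grid bin width changes choice probabilities < 1e-3", {
  set.seed(22)
  ds <- generate_dataset(10, mixture = c(accumulation = 1))
  for (i in seq_len(nrow(ds))) {
    p1 <- choice_probability(ds[i, ], th_meta, grid_dx = 0.05)
    p2 <- choice_probability(ds[i, ], th_meta, grid_dx = 0.025)
    expect_lt(abs(p1 - p2), 1e-3)
  }
})

test_that("noise-free limit is a point mass at the click difference", {
  tr <- one_trial(c(0.1, 0.2), c(0.05, 0.15, 0.3, 0.4, 0.45), 0.5)
  g <- propagate_density(tr, ideal_params())
  m <- sum(g$x * g$mass)
  v <- sum((g$x - m)^2 * g$mass)
  expect_equal(m, 3, tolerance = 1e-9)      # mean preserved exactly
  expect_lt(sqrt(v), 0.05)                  # spread at grid tolerance
  expect_equal(choice_probability(tr, ideal_params()), 1, tolerance = 1e-9)
})

test_that("no-click diffusion matches the closed-form Gaussian", {
  p <- accum_params(lambda = 0, sigma_a2 = 4, sigma_i2 = 1, B = 30,
                    phi = 1, tau_phi = 0.1, sho = 0.7)
  tr <- one_trial(numeric(0), numeric(0), 1)
  # B = 30 is ~13 sd: absorption negligible, terminal density ~ N(0, 5)
  expect_equal(choice_probability(tr, p),
               pnorm(0.7, 0, sqrt(5), lower.tail = FALSE), tolerance = 1e-3)
  # with a tight bound, absorbed + interior must match a Monte-Carlo oracle
  p2 <- accum_params(lambda = 0, sigma_a2 = 4, sigma_i2 = 1, B = 3,
                     phi = 1, tau_phi = 0.1, sho = 0)
  g <- propagate_density(tr, p2)
  set.seed(23)
  npath <- 2e5
  a <- rnorm(npath, 0, 1)
  alive <- abs(a) < 3
  a[alive] <- a[alive] + rnorm(sum(alive), 0, 2)
  mc_hi <- mean(a >= 3)
  expect_lt(abs(g$absorbed_hi - mc_hi), 3 * sqrt(mc_hi * (1 - mc_hi) / npath))
})

test_that("lapse = 1 gives probability 1/2 and log-likelihood n*ln(1/2)", {
  p <- with_params(th_meta, lapse = 1)
  tr <- one_trial(0.1, c(0.2, 0.3), 0.5)
  expect_identical(choice_probability(tr, p), 0.5)
  set.seed(24)
  ds <- generate_dataset(40, mixture = c(accumulation = 1))
  ds <- simulate_choices(ds, th_meta)
  expect_equal(log_likelihood(ds, p), 40 * log(0.5), tolerance = 1e-12)
})

test_that("post-categorization reversal sets easy-trial asymptotes", {
  # easiest possible rightward stimulus, reversal of 49.8% of R decisions
  tr <- one_trial(numeric(0), sort(runif(50, 0, 0.5)), 0.5)
  b <- bias_extension(kappa_R = 0.498)
  p <- choice_probability(tr, ideal_params(B = 30), bias = b)
  expect_equal(p, 0.502, tolerance = 1e-9)
})

test_that("appending a trial strictly decreases the log-likelihood", {
  set.seed(25)
  ds <- generate_dataset(20, mixture = c(accumulation = 1))
  ds <- simulate_choices(ds, th_meta)
  ll_all <- log_likelihood(ds, th_meta)
  ll_head <- log_likelihood(ds[1:19, ], th_meta)
  expect_lt(ll_all, ll_head)
})

test_that("batched likelihood equals the per-trial density path", {
  set.seed(26)
  ds <- generate_dataset(25, mixture = c(accumulation = 1))
  ds <- simulate_choices(ds, th_meta)
  p_each <- vapply(seq_len(nrow(ds)), function(i)
    choice_probability(ds[i, ], th_meta), numeric(1))
  ll_each <- sum(log(ifelse(ds$choice == "R", p_each, 1 - p_each)))
  expect_equal(log_likelihood(ds, th_meta), ll_each, tolerance = 1e-9)
})

test_that("density probabilities match Monte-Carlo simulation", {
  set.seed(27)
  thetas <- list(th_meta, reference_fits("bilateral_fof"))
  hits <- 0L
  tot <- 0L
  npath <- 20000
  for (p in thetas) {
    ds <- generate_dataset(20, mixture = c(accumulation = 1))
    for (i in seq_len(nrow(ds))) {
      pd <- choice_probability(ds[i, ], p)
      wr <- pclicks:::simulate_trial_paths(ds$left_clicks[[i]],
                                           ds$right_clicks[[i]],
                                           ds$duration[i], p, n = npath)
      pm <- mean(wr)
      se <- max(sqrt(pm * (1 - pm) / npath), 1e-4)
      hits <- hits + (abs(pd - pm) <= 3 * se)
      tot <- tot + 1L
    }
  }
  expect_gte(hits / tot, 0.9)
})

test_that("leak weights late clicks more; instability weights early ones", {
  p0 <- accum_params(sigma_s2 = 16, sigma_i2 = 0.5, B = 30, phi = 1,
                     tau_phi = 0.1)
  base <- one_trial(c(0.05, 0.25, 0.45), c(0.15, 0.35), 0.5)
  early <- one_trial(c(0.05, 0.25, 0.45), c(0.02, 0.15, 0.35), 0.5)
  late <- one_trial(c(0.05, 0.25, 0.45), c(0.15, 0.35, 0.48), 0.5)
  for (lam in c(-4, 4)) {
    p <- with_params(p0, lambda = lam)
    d_early <- choice_probability(early, p) - choice_probability(base, p)
    d_late <- choice_probability(late, p) - choice_probability(base, p)
    if (lam < 0) expect_gt(d_late, d_early) else expect_gt(d_early, d_late)
  }
})

test_that("mirroring the stimulus maps P(R) onto 1 - P(R)", {
  set.seed(28)
  ds <- generate_dataset(6, mixture = c(accumulation = 1))
  b <- bias_extension(kappa_L = 0.1, kappa_R = 0.25)
  bm <- bias_extension(kappa_L = 0.25, kappa_R = 0.1)
  for (i in seq_len(nrow(ds))) {
    tr <- one_trial(ds$left_clicks[[i]], ds$right_clicks[[i]],
                    ds$duration[i])
    mir <- one_trial(ds$right_clicks[[i]], ds$left_clicks[[i]],
                     ds$duration[i])
    p1 <- choice_probability(tr, th_meta, bias = b)
    p2 <- choice_probability(mir, with_params(th_meta, sho = -th_meta$sho),
                             bias = bm)
    # exact up to the (side-asymmetric) alignment of the decimated
    # convolution grid, which is well below any statistical resolution
    expect_equal(p1, 1 - p2, tolerance = 1e-4)
  }
})

test_that("invalid likelihood inputs are rejected", {
  tr <- generate_trial(20, 20, 0.5, seed = 29)
  expect_error(choice_probability(tr, with_params(th_meta, sho = 20)),
               "outside")
  expect_error(propagate_density(tr, th_meta, grid_dx = -1), "grid_dx")
  ds <- generate_dataset(5, mixture = c(accumulation = 1), seed = 30)
  expect_error(log_likelihood(ds, th_meta), "choice")
})
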