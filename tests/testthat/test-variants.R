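# Lateralized bias variants, ipsi/contra bookkeeping and their invariants.

th_meta <- meta_rat_params()

test_that("variants free exactly the documented parameters", {
  expect_equal(make_variant("post_cat", th_meta)$free, "kappa_contra")
  expect_equal(make_variant("gain", th_meta)$free, "gain_contra")
  expect_equal(make_variant("shift", th_meta)$free, "shift")
  expect_equal(make_variant("noise", th_meta)$free, "sigma_s2_contra")
  e8 <- make_variant("eight_param", th_meta)
  expect_length(e8$free, 8)
  expect_setequal(e8$free, c("lambda", "sigma_a2", "sigma_s2_ipsi", "shift",
                             "kappa_ipsi", "sigma_s2_contra", "gain_contra",
                             "kappa_contra"))
  expect_equal(make_variant("input_gain", th_meta)$free, "gain_contra")
  expect_length(make_variant("full_9param", th_meta)$free, 9)
  expect_error(make_variant("bogus", th_meta), "unknown variant")
})

test_that("free ipsi/contra parameters map onto the correct physical side", {
  sp <- make_variant("post_cat", th_meta, ipsi_side = "R")
  mdl <- pclicks:::build_model(sp, 0.4)
  expect_equal(mdl$bias$kappa_L, 0.4)   # contra of a right-side perturbation
  expect_equal(mdl$bias$kappa_R, 0)
  spL <- make_variant("gain", th_meta, ipsi_side = "L")
  mdlL <- pclicks:::build_model(spL, 1.7)
  expect_equal(mdlL$bias$gain_R, 1.7)
  expect_equal(mdlL$bias$gain_L, 1)     # ipsilateral gain pinned to 1
})

test_that("variant bias is the contra minus ipsi parameter difference", {
  sp <- make_variant("post_cat", th_meta)
  fit <- structure(list(par = c(kappa_contra = 0.4588), spec = sp),
                   class = "fit_result")
  expect_equal(unname(variant_bias(fit)), 0.4588)
  # a fit at the control value has zero bias under every paired variant
  for (v in c("post_cat", "gain", "noise")) {
    spv <- make_variant(v, th_meta)
    fit0 <- structure(list(par = pclicks:::control_theta(spv), spec = spv),
                      class = "fit_result")
    expect_equal(unname(variant_bias(fit0)), 0)
  }
  sps <- make_variant("shift", th_meta)
  fits <- structure(list(par = c(shift = 0.33), spec = sps),
                    class = "fit_result")
  expect_equal(unname(variant_bias(fits)), 0.33)
})

test_that("ipsi/contra relabeling mirrors left-side sessions, involutively", {
  set.seed(31)
  ds <- generate_dataset(30, mixture = c(accumulation = 1),
                         condition = "left_infusion")
  ds <- simulate_choices(ds, th_meta)
  rl <- relabel_ipsi_contra(ds)
  expect_identical(rl$choice, ifelse(ds$choice == "R", "L", "R"))
  expect_identical(rl$left_clicks[[3]], ds$right_clicks[[3]])
  twice <- relabel_ipsi_contra(rl)
  expect_identical(as.data.frame(twice)[, 1:14], as.data.frame(ds)[, 1:14])
  # a right infusion is already in the ipsi = R frame
  dsr <- generate_dataset(10, mixture = c(accumulation = 1), seed = 32,
                          condition = "right_infusion")
  dsr <- simulate_choices(dsr, th_meta, seed = 33)
  expect_identical(relabel_ipsi_contra(dsr)$choice, dsr$choice)
  expect_error(relabel_ipsi_contra(generate_dataset(5, seed = 34)),
               "infusion")
})

test_that("accumulator shift is equivalent to moving the decision boundary", {
  set.seed(35)
  ds <- generate_dataset(30, mixture = c(accumulation = 1))
  ds <- simulate_choices(ds, th_meta)
  s <- 0.6
  ll_shift <- log_likelihood(ds, th_meta, bias_extension(shift = s))
  ll_sho <- log_likelihood(ds, with_params(th_meta, sho = th_meta$sho - s))
  expect_equal(ll_shift, ll_sho, tolerance = 1e-12)
})

test_that("kappa-induced bias is independent of trial difficulty", {
  # noise-free: any correct-side certainty is scaled identically by kappa
  b <- bias_extension(kappa_L = 0.3)        # contra = L under ipsi = R
  easy <- one_trial(sort(runif(2, 0, 0.5)), sort(runif(40, 0, 0.5)), 0.5)
  hard <- one_trial(sort(runif(19, 0, 0.5)), sort(runif(20, 0, 0.5)), 0.5)
  pe <- choice_probability(easy, ideal_params(B = 100), bias = b)
  ph <- choice_probability(hard, ideal_params(B = 100), bias = b)
  expect_equal(pe, 1, tolerance = 1e-9)     # R decisions never flipped
  expect_equal(ph, 1, tolerance = 1e-9)
  # contra-favoring trials are flipped by exactly kappa regardless of ease
  easyL <- one_trial(sort(runif(40, 0, 0.5)), sort(runif(2, 0, 0.5)), 0.5)
  hardL <- one_trial(sort(runif(20, 0, 0.5)), sort(runif(19, 0, 0.5)), 0.5)
  expect_equal(choice_probability(easyL, ideal_params(B = 100), bias = b),
               0.3, tolerance = 1e-9)
  expect_equal(choice_probability(hardL, ideal_params(B = 100), bias = b),
               0.3, tolerance = 1e-9)
})
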