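# shared test helpers: parameter tweaking and fast in-memory trial sets

with_params <- function(params, ...) {
  do.call(accum_params, utils::modifyList(unclass(params), list(...)))
}

# noise-free perfect-integrator regime: choice = sign(#R - #L)
ideal_params <- function(B = 1000, sho = 0) {
  accum_params(lambda = 0, sigma_a2 = 0, sigma_s2 = 0, sigma_i2 = 0,
               B = B, phi = 1, tau_phi = 0.1, sho = sho, lapse = 0)
}

# build a trial set directly from per-trial click counts (vectorized; avoids
# the per-row constructors when tests need 10^4 trials)
trials_from_counts <- function(n_left, n_right, duration = 0.5,
                               choice = NULL, session_id = "S001") {
  n <- length(n_left)
  lc <- lapply(seq_len(n), function(i)
    sort(stats::runif(n_left[i], 0, duration)))
  rc <- lapply(seq_len(n), function(i)
    sort(stats::runif(n_right[i], 0, duration)))
  df <- data.frame(
    trial_id = seq_len(n), rat_id = "synthetic", session_id = session_id,
    trial_type = "accumulation", duration = duration,
    left_clicks = I(lc), right_clicks = I(rc),
    generative_rate_left = n_left / duration,
    generative_rate_right = n_right / duration,
    correct_side = ifelse(n_right > n_left, "R",
                          ifelse(n_left > n_right, "L", "either")),
    choice = if (is.null(choice)) "none" else choice,
    condition = "control", region = "none", dose = 0,
    stringsAsFactors = FALSE)
  pclicks:::new_trial_set(df)
}

one_trial <- function(left, right, duration) {
  list(left_clicks = left, right_clicks = right, duration = duration)
}
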