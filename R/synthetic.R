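trial_types <- c("accumulation", "single_sided", "side_led", "free_choice")

new_trial_set <- function(df, mixture = NULL, seed = NULL) {
  if (anyDuplicated(df$trial_id)) stop("trial_ids must be unique")
  structure(df, class = c("trial_set", "data.frame"),
            mixture = mixture, seed = seed)
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d trials (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$trial_type)),
                            table(x$trial_type)), collapse = ", ")))
  invisible(x)
}

majority_side <- function(n_left, n_right) {
  ifelse(n_right > n_left, "R", ifelse(n_left > n_right, "L", "either"))
}

trial_row <- function(trial_id, trial_type, duration, left, right,
                      rate_left, rate_right, correct_side,
                      rat_id = "synthetic", session_id = "S001",
                      condition = "control", region = "none", dose = 0) {
  data.frame(trial_id = as.integer(trial_id), rat_id = rat_id,
             session_id = session_id, trial_type = trial_type,
             duration = duration,
             left_clicks = I(list(left)), right_clicks = I(list(right)),
             generative_rate_left = rate_left,
             generative_rate_right = rate_right,
             correct_side = correct_side, choice = "none",
             condition = condition, region = region, dose = dose,
             stringsAsFactors = FALSE)
}

#' Generate one Poisson click-train trial
#'
#' Left and right click trains are two independent Poisson processes: counts
#' are Poisson(rate x duration) and, given the counts, click times are i.i.d.
#' uniform on [0, duration]. The correct side is the side with the larger
#' realized click count (ties give \code{"either"}).
#'
#' @param rate_left,rate_right generative click rates (clicks/s, >= 0).
#' @param duration stimulus duration in seconds; accumulation trials must lie
#'   in [0.1, 1].
#' @param trial_type one of \code{"accumulation"}, \code{"single_sided"}.
#' @param seed optional integer seed.
#' @param ... identification fields passed to the trial record.
#' @return A one-row trial set.
#' @export
generate_trial <- function(rate_left, rate_right, duration,
                           trial_type = "accumulation", seed = NULL, ...) {
  if (rate_left < 0 || rate_right < 0) stop("click rates must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  if (trial_type == "accumulation" && (duration < 0.1 || duration > 1))
    stop("accumulation trials must have duration in [0.1, 1] s")
  if (!is.null(seed)) set.seed(seed)
  left <- sort(stats::runif(stats::rpois(1, rate_left * duration),
                            0, duration))
  right <- sort(stats::runif(stats::rpois(1, rate_right * duration),
                             0, duration))
  new_trial_set(trial_row(1L, trial_type, duration, left, right,
                          rate_left, rate_right,
                          majority_side(length(left), length(right)), ...))
}

#' Generate a single-sided control trial
#'
#' All clicks come from one speaker at a Poisson rate of 100 clicks/s -- an
#' unusually easy stimulus requiring no accumulation; the fixed 100 Hz rate
#' is part of the trial type's definition and ignores the accumulation-trial
#' rate total.
#'
#' @param side \code{"L"} or \code{"R"}.
#' @param duration stimulus duration (s).
#' @inheritParams generate_trial
#' @return A one-row trial set with \code{trial_type = "single_sided"} and
#'   \code{correct_side = side}.
#' @export
generate_single_sided_trial <- function(side, duration, seed = NULL, ...) {
  side <- match.arg(side, c("L", "R"))
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, 100 * duration)
  clicks <- sort(stats::runif(n, 0, duration))
  left <- if (side == "L") clicks else numeric(0)
  right <- if (side == "R") clicks else numeric(0)
  ts <- new_trial_set(trial_row(1L, "single_sided", duration, left, right,
                                if (side == "L") 100 else 0,
                                if (side == "R") 100 else 0, side, ...))
  ts$correct_side <- side   # defined by the stimulated side, not realized ties
  ts
}

#' Default difficulty ladder
#'
#' Eight symmetric (rate_left, rate_right) pairs summing to
#' \code{total_rate}, with log-ratio magnitudes log-spaced from near-chance
#' to the easiest 39:1 split, mirrored across sides so left and right roles
#' are counterbalanced.
#'
#' @param n_pairs even number of pairs (default 8).
#' @param total_rate summed click rate (clicks/s, default 40).
#' @param max_ratio largest rate ratio (default 39, i.e. 39:1).
#' @return Data frame with columns \code{rate_left}, \code{rate_right}.
#' @export
default_difficulty_set <- function(n_pairs = 8, total_rate = 40,
                                   max_ratio = 39) {
  stopifnot(n_pairs %% 2 == 0, n_pairs >= 2)
  lr <- log(max_ratio) / 2^(seq_len(n_pairs / 2) - 1)
  lr <- c(lr, -lr)
  rate_right <- total_rate * stats::plogis(lr)
  data.frame(rate_left = total_rate - rate_right, rate_right = rate_right)
}

#' Generate a synthetic session of mixed trial types
#'
#' Trial types are assigned multinomially according to \code{mixture};
#' accumulation trials draw a difficulty pair uniformly from
#' \code{difficulty_set} (mirrored pairs counterbalance sides) and a duration
#' uniformly from \code{duration_range}; single-sided trials play 100 Hz on
#' one (equiprobable) side; side-LED and free-choice trials carry no clicks.
#' Choices are left unset (\code{"none"}); see \code{\link{simulate_choices}}.
#'
#' @param n_trials number of trials.
#' @param mixture named proportions over
#'   \code{accumulation/single_sided/side_led/free_choice}; must sum to 1.
#' @param difficulty_set data frame of generative rate pairs.
#' @param duration_range range (s) of the uniformly drawn stimulus duration.
#' @param seed optional integer seed; identical seeds give identical sets.
#' @param rat_id,session_id,condition,region,dose identification fields.
#' @return A \code{trial_set} data frame.
#' @export
generate_dataset <- function(n_trials,
                             mixture = c(accumulation = 0.9, side_led = 0.1),
                             difficulty_set = default_difficulty_set(),
                             duration_range = c(0.1, 1), seed = NULL,
                             rat_id = "synthetic", session_id = "S001",
                             condition = "control", region = "none",
                             dose = 0) {
  if (!all(names(mixture) %in% trial_types))
    stop("unknown trial type in mixture")
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  if ((mixture["accumulation"] %||% 0) > 0 &&
      (is.null(difficulty_set) || nrow(difficulty_set) == 0))
    stop("non-empty difficulty_set required for accumulation trials")
  if (!is.null(seed)) set.seed(seed)

  types <- sample(names(mixture), n_trials, replace = TRUE, prob = mixture)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tt <- types[i]
    dur <- stats::runif(1, duration_range[1], duration_range[2])
    if (tt == "accumulation") {
      d <- difficulty_set[sample.int(nrow(difficulty_set), 1), ]
      left <- sort(stats::runif(stats::rpois(1, d$rate_left * dur), 0, dur))
      right <- sort(stats::runif(stats::rpois(1, d$rate_right * dur), 0, dur))
      rows[[i]] <- trial_row(i, tt, dur, left, right, d$rate_left,
                             d$rate_right,
                             majority_side(length(left), length(right)),
                             rat_id, session_id, condition, region, dose)
    } else if (tt == "single_sided") {
      side <- sample(c("L", "R"), 1)
      n <- stats::rpois(1, 100 * dur)
      clk <- sort(stats::runif(n, 0, dur))
      rows[[i]] <- trial_row(i, tt, dur,
                             if (side == "L") clk else numeric(0),
                             if (side == "R") clk else numeric(0),
                             if (side == "L") 100 else 0,
                             if (side == "R") 100 else 0, side,
                             rat_id, session_id, condition, region, dose)
      rows[[i]]$correct_side <- side
    } else {
      cs <- if (tt == "side_led") sample(c("L", "R"), 1) else "either"
      rows[[i]] <- trial_row(i, tt, dur, numeric(0), numeric(0), 0, 0, cs,
                             rat_id, session_id, condition, region, dose)
    }
  }
  new_trial_set(do.call(rbind, rows), mixture = mixture, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Monte-Carlo sample paths of the accumulator for one stimulus; kept free of
# any density-propagation code so it can serve as an independent oracle.
simulate_trial_paths <- function(left, right, duration, params, bias = NULL,
                                 n = 1) {
  b <- resolve_bias(bias, params)
  ad <- adapt_clicks(left, right, params$phi, params$tau_phi)
  a <- stats::rnorm(n, 0, sqrt(params$sigma_i2))
  alive <- abs(a) < params$B
  t <- 0
  evolve <- function(a, alive, dt) {
    if (dt <= 0) return(list(a = a, alive = alive))
    mult <- exp(params$lambda * dt)
    v <- if (abs(params$lambda) < 1e-10) params$sigma_a2 * dt
         else params$sigma_a2 * expm1(2 * params$lambda * dt) /
              (2 * params$lambda)
    na <- sum(alive)
    if (na > 0)
      a[alive] <- a[alive] * mult + stats::rnorm(na, 0, sqrt(v))
    alive <- alive & abs(a) < params$B
    list(a = a, alive = alive)
  }
  for (k in seq_len(nrow(ad))) {
    st <- evolve(a, alive, ad$time[k] - t)
    a <- st$a; alive <- st$alive; t <- ad$time[k]
    na <- sum(alive)
    if (na > 0) {
      if (ad$side[k] > 0) {
        kick <- b$gain_R * ad$amplitude[k] *
          stats::rnorm(na, 1, sqrt(b$sigma_s2_R))
      } else {
        kick <- -b$gain_L * ad$amplitude[k] *
          stats::rnorm(na, 1, sqrt(b$sigma_s2_L))
      }
      a[alive] <- a[alive] + kick
      alive <- alive & abs(a) < params$B
    }
  }
  st <- evolve(a, alive, duration - t)
  a <- st$a
  went_right <- (a + b$shift) > params$sho
  if (params$lapse > 0) {
    lapsed <- stats::runif(n) < params$lapse
    went_right[lapsed] <- stats::runif(sum(lapsed)) < 0.5
  }
  u <- stats::runif(n)
  flip <- (went_right & u < b$kappa_R) | (!went_right & u < b$kappa_L)
  xor(went_right, flip)
}

#' Simulate a multi-session unilateral-perturbation study
#'
#' Generates \code{n_sessions} synthetic sessions (alternating left- and
#' right-side perturbations), draws choices from the accumulator model with
#' a post-categorization reversal of a fraction \code{kappa_contra} of
#' contralateral decisions (plus any extra bias fields in \code{bias}), and
#' relabels all trials into the common ipsi/contra frame (ipsi = "R").
#'
#' @param params generative \code{\link{accum_params}}.
#' @param n_sessions number of sessions.
#' @param trials_per_session trials per session.
#' @param kappa_contra fraction of contralateral decisions reversed.
#' @param seed integer seed.
#' @param mixture trial-type mixture per session.
#' @return A relabeled \code{trial_set} with one \code{session_id} per
#'   session and \code{condition} recording the perturbed side.
#' @export
simulate_unilateral_study <- function(params, n_sessions = 30,
                                      trials_per_session = 128,
                                      kappa_contra = 0.5, seed = NULL,
                                      mixture = c(accumulation = 1)) {
  if (!is.null(seed)) set.seed(seed)
  sets <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    side <- if (s %% 2 == 0) "L" else "R"
    cond <- if (side == "L") "left_infusion" else "right_infusion"
    ds <- generate_dataset(trials_per_session, mixture = mixture,
                           session_id = sprintf("S%03d", s),
                           condition = cond, region = "synthetic")
    # contra decisions (opposite the perturbed side) are reversed
    bias <- if (side == "R") bias_extension(kappa_L = kappa_contra,
                                            ipsi_side = "R")
            else bias_extension(kappa_R = kappa_contra, ipsi_side = "L")
    ds <- simulate_choices(ds, params, bias = bias)
    ds$trial_id <- ds$trial_id + (s - 1L) * trials_per_session
    sets[[s]] <- ds
  }
  out <- new_trial_set(do.call(rbind, sets), seed = seed)
  relabel_ipsi_contra(out)
}

#' Simulate choices from the generative accumulator model
#'
#' Draws choices for every trial of a set by exact forward simulation of the
#' accumulator: initial draw N(0, sigma_i2), adapted click kicks with
#' multiplicative noise, drift and diffusion between events, sticky
#' absorption at the bounds, categorization against the decision boundary,
#' then lapse and post-categorization reversals. With a large
#' \code{n_paths_per_trial} the per-trial empirical frequencies double as a
#' Monte-Carlo estimate of the model choice probabilities (column
#' \code{p_right_mc}).
#'
#' Side-LED and free-choice trials carry no clicks and are not simulated
#' through the accumulator; their choices come from simple preference
#' parameters (\code{side_led_accuracy}, \code{free_choice_p_right}),
#' intended for testing the surrounding bookkeeping only.
#'
#' @param trials a \code{trial_set}.
#' @param params \code{\link{accum_params}}.
#' @param bias optional \code{\link{bias_extension}} (e.g. a simulated
#'   unilateral perturbation).
#' @param n_paths_per_trial paths per trial; the recorded choice is always a
#'   single draw (the first path).
#' @param seed optional integer seed.
#' @param side_led_accuracy probability a side-LED trial follows the light.
#' @param free_choice_p_right probability a free-choice trial goes right.
#' @return The trial set with \code{choice} filled (and \code{p_right_mc}
#'   when \code{n_paths_per_trial > 1}).
#' @export
simulate_choices <- function(trials, params, bias = NULL,
                             n_paths_per_trial = 1, seed = NULL,
                             side_led_accuracy = 0.99,
                             free_choice_p_right = 0.5) {
  stopifnot(inherits(params, "accum_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trials$left_clicks) || is.null(trials$right_clicks))
    stop("simulate_choices: trials must carry click times")
  n <- nrow(trials)
  p_mc <- rep(NA_real_, n)
  choice <- character(n)
  for (i in seq_len(n)) {
    tt <- trials$trial_type[i]
    if (tt %in% ll_trial_types) {
      wr <- simulate_trial_paths(trials$left_clicks[[i]],
                                 trials$right_clicks[[i]],
                                 trials$duration[i], params, bias,
                                 n = n_paths_per_trial)
      choice[i] <- if (wr[1L]) "R" else "L"
      p_mc[i] <- mean(wr)
    } else if (tt == "side_led") {
      correct <- stats::runif(1) < side_led_accuracy
      choice[i] <- if (correct) trials$correct_side[i] else
        setdiff(c("L", "R"), trials$correct_side[i])
    } else {
      choice[i] <- if (stats::runif(1) < free_choice_p_right) "R" else "L"
    }
  }
  trials$choice <- choice
  if (n_paths_per_trial > 1) trials$p_right_mc <- p_mc
  trials
}
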