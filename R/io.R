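trial_table_columns <- c("rat_id", "session_id", "trial_id", "trial_type",
                         "duration_s", "left_clicks", "right_clicks",
                         "choice", "correct_side", "condition", "region",
                         "dose_ng", "generative_rate_left",
                         "generative_rate_right")

# scientific with 17 mantissa decimals: >= 18 significant digits, so every
# double round-trips exactly at any magnitude
fmt_time <- function(x) sprintf("%.17e", x)

fmt_clicks <- function(lst) {
  vapply(lst, function(v)
    if (length(v) == 0) "" else paste(fmt_time(v), collapse = ";"),
    character(1))
}

parse_clicks <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

# Tiny rolling hash so artifact files can embed which configuration wrote
# them (pure double arithmetic: R's bitwise ops cap at 2^31)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Write a trial table as delimited text
#'
#' Comma-separated UTF-8 with "." decimal marks; click-time lists are
#' semicolon-delimited seconds printed with enough digits to round-trip the
#' doubles exactly. A comment header records the generator seed and a hash of
#' the configuration that produced the data.
#'
#' @param trials a trial set.
#' @param path output file.
#' @param seed,config optional provenance recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(trials, path, seed = attr(trials, "seed"),
                         config = attr(trials, "mixture")) {
  df <- data.frame(
    rat_id = trials$rat_id, session_id = trials$session_id,
    trial_id = trials$trial_id, trial_type = trials$trial_type,
    duration_s = fmt_time(trials$duration),
    left_clicks = fmt_clicks(trials$left_clicks),
    right_clicks = fmt_clicks(trials$right_clicks),
    choice = trials$choice, correct_side = trials$correct_side,
    condition = trials$condition, region = trials$region,
    dose_ng = fmt_time(trials$dose),
    generative_rate_left = fmt_time(trials$generative_rate_left),
    generative_rate_right = fmt_time(trials$generative_rate_right),
    stringsAsFactors = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# pclicks trial table; seed=%s; config=%s",
                     if (is.null(seed)) "NA" else as.character(seed),
                     config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table
#'
#' Parses and validates a file written by \code{\link{write_trials}} (or any
#' delimited table with the same columns): click lists must be sorted
#' ascending and lie within [0, duration]; enumerated columns are checked.
#' Malformed rows raise an error naming the row and column. An empty file
#' with a valid header yields an empty trial set.
#'
#' @param path input file.
#' @return A \code{trial_set}.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("read_trials: no such file: ", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(trial_table_columns, names(raw))
  if (length(missing))
    stop("read_trials: missing column(s): ", paste(missing, collapse = ", "))
  n <- nrow(raw)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]))
    if (length(bad))
      stop("read_trials: row ", bad[1], ", column '", col, "': not numeric")
    v
  }
  duration <- num("duration_s")
  lc <- vector("list", n)
  rc <- vector("list", n)
  for (i in seq_len(n)) {
    for (col in c("left_clicks", "right_clicks")) {
      v <- parse_clicks(raw[[col]][i])
      if (anyNA(v))
        stop("read_trials: row ", i, ", column '", col, "': bad click list")
      if (is.unsorted(v))
        stop("read_trials: row ", i, ", column '", col, "': clicks not sorted")
      if (length(v) && (v[1] < 0 || v[length(v)] > duration[i]))
        stop("read_trials: row ", i, ", column '", col,
             "': click time outside [0, duration]")
      if (col == "left_clicks") lc[[i]] <- v else rc[[i]] <- v
    }
    if (!raw$trial_type[i] %in% trial_types)
      stop("read_trials: row ", i, ", column 'trial_type': unknown type")
    if (!raw$choice[i] %in% c("L", "R", "none"))
      stop("read_trials: row ", i, ", column 'choice': invalid value")
    if (!raw$correct_side[i] %in% c("L", "R", "either"))
      stop("read_trials: row ", i, ", column 'correct_side': invalid value")
  }
  df <- data.frame(
    trial_id = as.integer(num("trial_id")), rat_id = raw$rat_id,
    session_id = raw$session_id, trial_type = raw$trial_type,
    duration = duration, left_clicks = I(lc), right_clicks = I(rc),
    generative_rate_left = num("generative_rate_left"),
    generative_rate_right = num("generative_rate_right"),
    correct_side = raw$correct_side, choice = raw$choice,
    condition = raw$condition, region = raw$region, dose = num("dose_ng"),
    stringsAsFactors = FALSE)
  new_trial_set(df)
}

#' Default run configuration
#'
#' The resolved set of tunables a full analysis run records: seeds, grid
#' pitch, optimizer settings, trial mixture, difficulty ladder and variant
#' list. Serializable to YAML via \code{\link{write_run_config}}.
#' @return Named list.
#' @export
default_run_config <- function() {
  list(seed = 1L,
       grid_dx = 0.05,
       n_scan = 25,
       n_starts = 5,
       n_boot = 300,
       mh = list(n_chains = 4L, n_samples = 10000L, burnin = 100L, thin = 4L),
       mixture = list(accumulation = 0.65, free_choice = 0.25,
                      side_led = 0.10),
       duration_range = c(0.1, 1),
       total_rate = 40,
       variants = c("post_cat", "gain", "shift", "noise"),
       max_trials_per_session = 250)
}

#' Read / write run configuration (YAML)
#' @param path file path.
#' @return For \code{read_run_config}, the configuration list merged over
#'   the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Serialize a bootstrap result to a delimited matrix layout
#'
#' One row per resample, one column per refit parameter, plus the resample
#' log-likelihood; mirrors the standard resampled-fits matrix layout
#' (n_boot x parameters with a parallel LL vector and name list).
#' @param x a \code{bootstrap_result}.
#' @param path output csv.
#' @export
write_bootstrap_result <- function(x, path) {
  df <- as.data.frame(x$boot)
  df$ll <- x$ll
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# pclicks bootstrap; n_boot=%d; seed=%s; params=%s",
                     x$n_boot, if (is.null(x$seed)) "NA" else x$seed,
                     paste(colnames(x$boot), collapse = ";")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
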