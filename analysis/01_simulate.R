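#!/usr/bin/env Rscript
# Generate the synthetic datasets used throughout the analysis:
#   control sessions (pooled-control parameters), a bilateral-perturbation
#   style dataset (leaky-accumulator parameters), a 30-session unilateral
#   study with an injected post-categorization bias, and a free-choice
#   session mixture. All tables land in results/ as delimited text.
suppressPackageStartupMessages(library(pclicks))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

th_ctrl <- meta_rat_params()
th_bi <- reference_fits("bilateral_fof")

message("Control sessions: 5000 trials, 90% accumulation / 10% side LED")
ctrl <- generate_dataset(5000, mixture = c(accumulation = 0.9,
                                           side_led = 0.1), seed = seed)
ctrl <- simulate_choices(ctrl, th_ctrl, seed = seed + 1L)
write_trials(ctrl, "results/trials_control.csv")

message("Bilateral-perturbation style dataset: 1809 accumulation trials")
bi <- generate_dataset(1809, mixture = c(accumulation = 1), seed = seed + 2L,
                       condition = "bilateral", region = "synthetic")
bi <- simulate_choices(bi, th_bi, seed = seed + 3L)
write_trials(bi, "results/trials_bilateral.csv")

message("Unilateral study: 30 sessions x 128 trials, kappa_contra = 0.5")
uni <- simulate_unilateral_study(th_ctrl, n_sessions = 30,
                                 trials_per_session = 128,
                                 kappa_contra = 0.5, seed = seed + 4L)
write_trials(uni, "results/trials_unilateral.csv")

message("Free-choice sessions: 65/25/10 accumulation/free-choice/side-LED")
fc <- generate_dataset(2000, mixture = c(accumulation = 0.65,
                                         free_choice = 0.25,
                                         side_led = 0.10), seed = seed + 5L)
fc <- simulate_choices(fc, th_ctrl, seed = seed + 6L,
                       free_choice_p_right = 0.65)
write_trials(fc, "results/trials_free_choice.csv")

cfg <- default_run_config()
cfg$seed <- seed
write_run_config(cfg, "results/run_config.yaml")

acc <- function(x) {
  ok <- x$trial_type == "accumulation" & x$correct_side %in% c("L", "R")
  mean((x$choice == x$correct_side)[ok])
}
cat(sprintf("control accuracy (accumulation trials): %.1f%%\n",
            100 * acc(ctrl)))
cat(sprintf("bilateral-style accuracy:               %.1f%%\n",
            100 * acc(bi)))
cat(sprintf("unilateral ipsi choice fraction:        %.1f%%\n",
            100 * mean(uni$choice[uni$trial_type == "accumulation"] == "R")))
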