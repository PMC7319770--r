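#!/usr/bin/env Rscript
# Stage 2: amperometric trace metrics.
#
# Calibrates the electrode from known-concentration standards (the fit is
# rejected below r^2 = 0.98), converts the recorded current to dopamine
# concentration, blanks the electrical stimulus artefact, and reports peak
# amplitude, 20-80% rise time and windowed area under the curve. The
# estimates are then compared against the generator's ground truth.
# Run from the repository root:  Rscript analysis/02_trace_metrics.R [--seed N]
suppressPackageStartupMessages(library(dopaquant))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

# Calibration standards bracketing the expected signal range. The simulated
# electrode responds at 2 nA per uM with zero offset; a real session would
# use the measured bath responses here.
standards <- list(concentration_um = c(0.5, 1, 2, 4),
                  current_na = c(1.0, 2.0, 4.0, 8.0))

files <- run_stage("analyze-trace",
                   params = list(
                     trace_path = "results/raw/trace/trace_current.csv",
                     calibration = standards,
                     stim_onsets_s = 0.5,
                     blank_artefacts = TRUE,
                     artefact_blank_ms = 1.0,
                     baseline_window = c(0, 0.45),
                     search_window = c(0.5, 3.4),
                     auc_duration_s = 2.935),
                   seed = seed, out_dir = "results/trace")

est <- read.csv(files[["metrics"]])
truth <- jsonlite::read_json("results/raw/trace/trace_truth.json",
                             simplifyVector = TRUE)
cmp <- data.frame(
  metric = c("peak_amplitude", "rise_time_20_80", "auc"),
  estimate = est$value[match(c("peak_amplitude", "rise_time_20_80", "auc"),
                             est$metric)],
  truth = c(truth$true_peak_um, truth$true_rise_time_20_80_ms,
            truth$true_auc_um_s))
cmp$rel_error <- (cmp$estimate - cmp$truth) / cmp$truth
write.csv(cmp, "results/trace/trace_vs_truth.csv", row.names = FALSE)
print(cmp, digits = 4)
cat("trace metrics written under results/trace/\n")
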