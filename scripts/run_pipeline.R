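#!/usr/bin/env Rscript
# Thin command-line front end over the package:
#   Rscript scripts/run_pipeline.R run      --seed 1 --out out/run1
#   Rscript scripts/run_pipeline.R simulate --seed 1 --out out/sim1
# `run` simulates a cohort and performs the complete analysis; `simulate`
# only writes per-subject gaze/event CSVs plus the ground truth.

suppressPackageStartupMessages({
  library(optparse)
  library(nvsacc)
})

raw_args <- commandArgs(TRUE)
if (length(raw_args) && !startsWith(raw_args[1], "-")) {
  cmd <- raw_args[1]
  raw_args <- raw_args[-1]
} else {
  cmd <- "run"
}

parser <- OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "nvsacc_out"),
  make_option("--n-young", type = "integer", default = 28L, dest = "n_young"),
  make_option("--n-old", type = "integer", default = 26L, dest = "n_old"),
  make_option("--velocity-threshold", type = "double", default = 100,
              dest = "velocity_threshold"),
  make_option("--detection-mode", type = "character", default = "per_component",
              dest = "detection_mode"),
  make_option("--min-valid-fraction", type = "double", default = 0.70,
              dest = "min_valid_fraction"),
  make_option("--noise-sd-deg", type = "double", default = 0.12,
              dest = "noise_sd_deg"),
  make_option("--dropout-rate", type = "double", default = 0.05,
              dest = "dropout_rate")))
opt <- parse_args(parser, args = raw_args)

sim <- sim_config(n_young = opt$n_young, n_old = opt$n_old,
                  noise_sd_deg = opt$noise_sd_deg,
                  dropout_rate = opt$dropout_rate)
det <- detection_config(velocity_threshold = opt$velocity_threshold,
                        mode = opt$detection_mode)

if (cmd == "simulate") {
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  coh <- simulate_cohort(sim, seed = opt$seed)
  for (s in coh$subjects) {
    id <- s$trace$subject_id
    write_gaze(s$trace, file.path(opt$out, paste0(id, "_gaze.csv")))
    write_events(s$events, file.path(opt$out, paste0(id, "_events.csv")))
    jsonlite::write_json(s$truth, file.path(opt$out, paste0(id, "_truth.json")),
                         digits = NA)
  }
  data.table::fwrite(coh$demographics, file.path(opt$out, "demographics.csv"))
  cat("simulated", length(coh$subjects), "subjects into", opt$out, "\n")
} else {
  run_end_to_end(opt$out, seed = opt$seed, sim = sim, detection = det,
                 min_valid_fraction = opt$min_valid_fraction)
  cat("pipeline outputs written to", opt$out, "\n")
}
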