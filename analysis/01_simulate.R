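#!/usr/bin/env Rscript

## Step 1: simulate the cohort and write every sensor stream to disk in the
## plain-text formats the ingest step consumes.
##
## Problem size: 13 runners at a desk-scale race length (20 min) so the
## whole workflow reruns in about a minute; the generators scale linearly,
## so substituting the full-length durations only costs time.

suppressPackageStartupMessages(library(runfatigue))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

duration <- 1200
## spread the finish times so the cohort keeps distinct paces
durations <- duration * seq(0.85, 1.15, length.out = 13)
cfg <- sim_config(n_subjects = 13, race_duration = durations,
                  rof_interval_s = min(durations) / 9, seed = 20191027L)

## performance groups at this scale: 5 fastest, 5 slowest, 3 mid
rk <- rank(durations, ties.method = "first")
group <- ifelse(rk <= 5, "fast", ifelse(rk > 8, "slow", "mid"))

manifest <- data.frame(subject = integer(0), group = character(0),
                       duration_s = numeric(0), mass_kg = numeric(0))
for (s in seq_len(cfg$n_subjects)) {
  rec <- simulate_subject(cfg, s)
  sd_ <- file.path(out_dir, sprintf("subject_%02d", s))
  dir.create(sd_, showWarnings = FALSE)
  ## the device-like RR export is the artifact-injected series
  rr_out <- if (!is.null(rec$rr_corrupted)) rec$rr_corrupted else rec$rr
  utils::write.csv(data.frame(beat_time_s = rr_out$beat_time),
                   file.path(sd_, "rr.csv"), row.names = FALSE)
  utils::write.csv(rec$cycles, file.path(sd_, "cycles.csv"),
                   row.names = FALSE)
  write_gpx(rec$gnss, file.path(sd_, "track.gpx"))
  write_rof_csv(rec$rof, file.path(sd_, "rof.csv"))
  write_ground_truth_json(rec$truth, file.path(sd_, "truth.json"))
  manifest <- rbind(manifest,
                    data.frame(subject = s, group = group[s],
                               duration_s = rec$race_duration,
                               mass_kg = rec$mass))
}
utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                 row.names = FALSE)
cat(sprintf("wrote %d subjects to %s\n", nrow(manifest), out_dir))
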