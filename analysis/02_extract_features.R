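#!/usr/bin/env Rscript

## Step 2: ingest the on-disk recordings and run the per-subject analysis
## chain (slope exclusion, gait streams with outlier replacement, windowed
## heart-rate dynamics, eight-segment aggregation, ROF assignment).
## Writes per-subject feature tables plus the parameter streams that the
## association step consumes.

suppressPackageStartupMessages(library(runfatigue))

data_dir <- "results/data"
out_dir <- "results/features"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

manifest <- utils::read.csv(file.path(data_dir, "manifest.csv"))

assoc_bio <- c("t_c", "FSA", "k_vert", "v", "a_AP")
assoc_phy <- c("BPM", "SDNN", "DFA_a1", "SD2")

for (i in seq_len(nrow(manifest))) {
  s <- manifest$subject[i]
  sd_ <- file.path(data_dir, sprintf("subject_%02d", s))
  rec <- list(
    cycles = utils::read.csv(file.path(sd_, "cycles.csv")),
    rr = rr_series(utils::read.csv(file.path(sd_, "rr.csv"))$beat_time_s),
    gnss = read_gpx(file.path(sd_, "track.gpx")),
    rof = read_rof_csv(file.path(sd_, "rof.csv")),
    race_duration = manifest$duration_s[i]
  )
  an <- analyze_subject(rec)
  utils::write.csv(an$sfm,
                   file.path(out_dir, sprintf("sfm_%02d.csv", s)),
                   row.names = FALSE)
  utils::write.csv(an$hr_table,
                   file.path(out_dir, sprintf("hr_%02d.csv", s)),
                   row.names = FALSE)
  streams <- do.call(rbind, c(
    lapply(assoc_bio, function(p) {
      d <- an$gait_streams[[p]]
      data.frame(kind = "biomech", parameter = p,
                 time = d$time, value = d$value)
    }),
    lapply(assoc_phy, function(p) {
      d <- an$hr_streams[[p]]
      data.frame(kind = "physio", parameter = p,
                 time = d$time, value = d$value)
    })))
  utils::write.csv(streams,
                   file.path(out_dir, sprintf("streams_%02d.csv", s)),
                   row.names = FALSE)
  utils::write.csv(an$segments,
                   file.path(out_dir, sprintf("segments_%02d.csv", s)),
                   row.names = FALSE)
  cat(sprintf("subject %02d: %d feature rows, %d valid HR windows\n",
              s, nrow(an$sfm), sum(an$hr_table$valid)))
}
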