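#!/usr/bin/env Rscript

## Step 4: biomechanics-physiology association analysis. For every
## gait x heart-rate parameter pair, per subject and race segment, aligns
## the two streams on the heart-rate window grid and records Pearson and
## distance correlations.

suppressPackageStartupMessages(library(runfatigue))

feat_dir <- "results/features"
tab_dir <- "results/tables"
dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)

manifest <- utils::read.csv("results/data/manifest.csv")

bio <- list(); phy <- list(); segs <- list()
for (i in seq_len(nrow(manifest))) {
  s <- manifest$subject[i]
  st <- utils::read.csv(file.path(feat_dir, sprintf("streams_%02d.csv", s)))
  split_one <- function(kind) {
    d <- st[st$kind == kind, ]
    lapply(split(d[, c("time", "value")], d$parameter), function(x)
      x[order(x$time), ])
  }
  bio[[i]] <- split_one("biomech")
  phy[[i]] <- split_one("physio")
  segs[[i]] <- utils::read.csv(
    file.path(feat_dir, sprintf("segments_%02d.csv", s)))
}

records <- association_records(bio, phy, segs,
                               biomech_names = names(bio[[1]]),
                               physio_names = names(phy[[1]]))
utils::write.csv(records, file.path(tab_dir, "association_records.csv"),
                 row.names = FALSE)
summ <- summarize_associations(records)
utils::write.csv(summ, file.path(tab_dir, "association_summary.csv"),
                 row.names = FALSE)

n_sig <- sum(!is.na(records$p) & records$p < 0.05)
cat(sprintf("associations: %d records over %d pairs, %d significant\n",
            nrow(records), length(unique(records$pair)), n_sig))
cat("strongest pairs by median significant |r|:\n")
o <- order(-abs(summ$r_median))
print(utils::head(summ[o, ], 5), row.names = FALSE)
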