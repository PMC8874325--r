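#!/usr/bin/env Rscript

## Step 3: cohort-level statistics on the segment feature matrices --
## the non-parametric battery (Friedman + pairwise Wilcoxon over the three
## fatigue designs) and the fast/slow mixed-effects models.

suppressPackageStartupMessages(library(runfatigue))

feat_dir <- "results/features"
tab_dir <- "results/tables"
dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)

manifest <- utils::read.csv("results/data/manifest.csv")
sfm_list <- lapply(manifest$subject, function(s)
  utils::read.csv(file.path(feat_dir, sprintf("sfm_%02d.csv", s))))

battery <- run_battery(sfm_list)
utils::write.csv(battery, file.path(tab_dir, "battery.csv"),
                 row.names = FALSE)
sig <- battery[battery$stars != "", ]
cat(sprintf("battery: %d tests, %d significant at 0.05\n",
            nrow(battery), nrow(sig)))

lme_rows <- list()
for (p in c("t_c", "BPM", "DFA_a1")) {
  long <- lme_long(sfm_list, manifest$group, p)
  fit <- try(fit_lme(long), silent = TRUE)
  if (inherits(fit, "try-error")) {
    cat(sprintf("lme[%s]: not fitted (%s)\n", p,
                conditionMessage(attr(fit, "condition"))))
    next
  }
  fx <- fit$fixed
  fx$parameter <- p
  fx$r2_marginal <- fit$r2_marginal
  fx$r2_conditional <- fit$r2_conditional
  fx$singular <- fit$singular
  lme_rows[[p]] <- fx
  cat(sprintf("lme[%s]: drof slope %.4f, R2c %.3f%s\n", p,
              fx$estimate[fx$term == "drof"], fit$r2_conditional,
              if (fit$singular) " (intercept-only refit)" else ""))
}
utils::write.csv(do.call(rbind, lme_rows),
                 file.path(tab_dir, "lme_fixed.csv"), row.names = FALSE)
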