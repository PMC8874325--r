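## End-to-end per-subject and cohort analysis.

biomech_params <- c("t_c", "t_f", "t_s", "t_g", "cadence", "D_f", "FSA",
                    "FEA", "omega_s", "k_vert", "v", "a_AP", "a_ML")
physio_params <- c("BPM", "SDNN", "RMSSD", "LF", "HF", "pLF", "pHF",
                   "LF_HF", "SD1", "SD2", "SD1_SD2", "DFA_a1", "DFA_a2",
                   "CC")

#' Analyse one subject's race recording
#'
#' Full single-subject chain: slope exclusion from the GNSS track, per-cycle
#' gait parameter streams (first/last steps trimmed, 2-SD outliers replaced
#' per race segment), heart-rate dynamics features on 120 s / 110 s-overlap
#' windows, eight-segment aggregation with reference normalization, and the
#' ROF assignment.
#'
#' @param rec a [simulate_subject()] recording (or an equivalently shaped
#'   list built from files: `cycles`, `rr`, `gnss`, `rof`,
#'   `race_duration`).
#' @param n_segments number of race segments.
#' @param trim steps trimmed at each race end.
#' @param grade_threshold,grade_window slope-exclusion parameters (%, m).
#' @param use_corrupted analyse the artifact-injected RR series when
#'   available (exercises the correction stage) rather than the clean one.
#' @return list with `sfm` (the [segment_feature_matrix()]), `segments`,
#'   `gait_streams`, `hr_streams` (named lists of data.frame(time, value)),
#'   `hr_table`, `mask` and `rof`.
#' @export
analyze_subject <- function(rec, n_segments = 8, trim = 10,
                            grade_threshold = 5, grade_window = 100,
                            use_corrupted = TRUE) {
  duration <- rec$race_duration
  segments <- split_race(0, duration, n_segments)
  ## slope exclusion
  mask <- if (!is.null(rec$gnss)) {
    detect_slopes(rec$gnss, grade_threshold, grade_window)
  } else {
    exclusion_mask(numeric(0), numeric(0), character(0))
  }
  ## gait streams from the per-cycle table
  cyc <- trim_steps(rec$cycles, trim)
  cyc_t <- cyc$start_time + cyc$t_g / 2
  gait_streams <- list()
  for (p in intersect(biomech_params, names(cyc))) {
    d <- data.frame(time = cyc_t, value = cyc[[p]])
    d <- exclude_intervals(d, mask)
    d$value <- remove_outliers_2sd(d$value, d$time,
                                   as.matrix(segments[, c("start", "end")]))
    gait_streams[[p]] <- d
  }
  ## heart-rate features
  rr <- if (use_corrupted && !is.null(rec$rr_corrupted)) {
    rec$rr_corrupted
  } else {
    rec$rr
  }
  speed <- if (!is.null(rec$gnss)) {
    data.frame(time = rec$gnss$time, speed = rec$gnss$speed)
  } else if (!is.null(gait_streams$v)) {
    data.frame(time = gait_streams$v$time, speed = gait_streams$v$value)
  } else NULL
  hr_tab <- hr_features(rr, speed)
  hr_streams <- list()
  for (p in intersect(physio_params, names(hr_tab))) {
    d <- data.frame(time = hr_tab$window_center, value = hr_tab[[p]])
    d <- exclude_intervals(d, mask)
    hr_streams[[p]] <- d
  }
  kinds <- c(stats::setNames(rep("biomech", length(gait_streams)),
                             names(gait_streams)),
             stats::setNames(rep("physio", length(hr_streams)),
                             names(hr_streams)))
  sfm <- segment_feature_matrix(c(gait_streams, hr_streams), kinds,
                                rec$rof, 0, duration, n_segments,
                                speed_stream = gait_streams$v)
  list(sfm = sfm, segments = segments, gait_streams = gait_streams,
       hr_streams = hr_streams, hr_table = hr_tab, mask = mask,
       rof = rec$rof)
}

#' Analyse a simulated cohort end to end
#'
#' Runs [analyze_subject()] for every recording, the non-parametric
#' statistical battery across the three designs, the fast/slow
#' linear-mixed-effects models and the association analysis.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param groups per-subject group labels; defaults to the recordings'
#'   labels.
#' @param lme_parameters parameters to model with [fit_lme()].
#' @param battery_designs designs passed to [run_battery()].
#' @param ... passed to [analyze_subject()].
#' @return list with `subjects` (per-subject analyses), `sfm_list`,
#'   `battery`, `lme` (named list of [fit_lme()] results), `associations`
#'   (records) and `association_summary`.
#' @export
analyze_cohort <- function(cohort, groups = NULL,
                           lme_parameters = c("t_c", "BPM", "DFA_a1"),
                           battery_designs = c("segments", "rof_levels",
                                               "drof_states"),
                           ...) {
  subjects <- lapply(cohort, analyze_subject, ...)
  sfm_list <- lapply(subjects, `[[`, "sfm")
  if (is.null(groups)) {
    groups <- vapply(cohort, function(r)
      if (is.null(r$group)) "mid" else r$group, "")
  }
  battery <- run_battery(sfm_list, designs = battery_designs)
  lme <- list()
  for (p in lme_parameters) {
    long <- lme_long(sfm_list, groups, p)
    fit <- try(fit_lme(long), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      fit$model <- NULL  # keep the result serialisable/light
      lme[[p]] <- fit
    }
  }
  bio <- lapply(subjects, function(s)
    s$gait_streams[c("t_c", "FSA", "k_vert", "v", "a_AP")])
  phy <- lapply(subjects, function(s)
    s$hr_streams[c("BPM", "SDNN", "DFA_a1", "SD2")])
  segs <- lapply(subjects, `[[`, "segments")
  records <- association_records(bio, phy, segs)
  list(subjects = subjects, sfm_list = sfm_list, battery = battery,
       lme = lme, associations = records,
       association_summary = summarize_associations(records))
}
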