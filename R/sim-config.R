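#' Simulation configuration for a synthetic race cohort
#'
#' Builds the configuration object consumed by all generators in the
#' synthetic-data module. Defaults emulate a 13-runner half-marathon cohort:
#' race times spanning roughly 82--118 min so that five runners finish under
#' 90 min ("fast") and five over 105 min ("slow"), an in-race RR interval
#' around 0.42 s drifting downwards (cardiovascular drift), weak LF/HF
#' oscillations on top of fractal (fGn) beat-to-beat noise, and linear
#' fatigue trends on the gait parameters whose signs follow what is commonly
#' reported for prolonged running (contact time and trunk-acceleration ratios
#' up; foot strike angle, flight time and swing velocity down).
#'
#' @param n_subjects number of runners.
#' @param race_duration numeric vector (recycled to `n_subjects`) of race
#'   durations in seconds.
#' @param mean_speed running speed in m/s per subject; default derived from a
#'   21,097.5 m half-marathon distance and `race_duration`.
#' @param rr_baseline baseline RR interval in seconds.
#' @param rr_drift_slope change of mean RR (s) per unit race fraction;
#'   negative values emulate cardiovascular drift (rising heart rate).
#' @param hurst_alpha_target target DFA short-term scaling exponent of the
#'   fractal noise component.
#' @param lf_amp,hf_amp amplitudes (s) of sinusoidal RR modulation at 0.1 Hz
#'   and 0.3 Hz.
#' @param rr_noise_sd standard deviation (s) of the fractal noise component.
#' @param artifact_rate fraction of beats perturbed when artifacts are
#'   injected; must lie in [0, 0.5).
#' @param cadence stride cadence in strides/min (one stride = one full gait
#'   cycle of the instrumented foot).
#' @param trends named list of per-parameter relative linear drifts over the
#'   race (e.g. `t_c = 0.05` means +5% from start to finish). Recognised
#'   names: t_c, t_f, FSA, FEA, omega_s, a_AP, a_ML, cadence, v.
#' @param trend_noise_sd named list (same names) of white-noise standard
#'   deviations expressed as a fraction of the parameter baseline.
#' @param baselines named list of parameter baselines: t_c (s), t_f (s),
#'   FSA (deg), FEA (deg), omega_s (deg/s), a_AP, a_ML ((m/s^2)/(m/s)).
#' @param mass body mass in kg per subject (recycled).
#' @param slope_sections matrix/data.frame with columns start_m, length_m,
#'   grade_pct describing climbing sections of the course, or NULL.
#' @param rof_start,rof_end first and last rating-of-fatigue values (1--10)
#'   of the default non-decreasing schedule.
#' @param rof_interval_s spacing of ROF prompts in seconds (600 s in the
#'   emulated protocol).
#' @param sync_lag clock offset in seconds between chest and foot sensors.
#' @param ecg_fs,imu_fs_chest,imu_fs_foot,gnss_fs sampling rates in Hz.
#' @param ecg_snr_db ECG signal-to-noise ratio in dB (Inf = noise free).
#' @param seed master integer seed; all per-subject substreams derive from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 13L,
                       race_duration = 60 * c(82, 84, 86, 88, 89, 95, 98.4,
                                              101, 106, 109, 112, 115, 118),
                       mean_speed = NULL,
                       rr_baseline = 0.42,
                       rr_drift_slope = -0.05,
                       hurst_alpha_target = 0.75,
                       lf_amp = 0.006,
                       hf_amp = 0.008,
                       rr_noise_sd = 0.01,
                       artifact_rate = 0.02,
                       cadence = 85,
                       trends = list(t_c = 0.05, t_f = -0.03, FSA = -0.08,
                                     FEA = 0.02, omega_s = -0.04,
                                     a_AP = 0.10, a_ML = 0.03,
                                     cadence = 0.0, v = 0.0),
                       trend_noise_sd = list(t_c = 0.02, t_f = 0.04,
                                             FSA = 0.04, FEA = 0.05,
                                             omega_s = 0.03, a_AP = 0.05,
                                             a_ML = 0.05, cadence = 0.01,
                                             v = 0.02),
                       baselines = list(t_c = 0.26, t_f = 0.11, FSA = 12,
                                        FEA = 8, omega_s = 600,
                                        a_AP = 0.30, a_ML = 0.12),
                       mass = 70,
                       slope_sections = NULL,
                       rof_start = 3L,
                       rof_end = 9L,
                       rof_interval_s = 600,
                       sync_lag = 0.35,
                       ecg_fs = 250,
                       imu_fs_chest = 200,
                       imu_fs_foot = 512,
                       gnss_fs = 10,
                       ecg_snr_db = 20,
                       seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop_config("n_subjects must be >= 1")
  race_duration <- rep_len(as.numeric(race_duration), n_subjects)
  if (any(race_duration <= 0)) stop_config("race_duration must be positive")
  if (is.null(mean_speed)) mean_speed <- 21097.5 / race_duration
  mean_speed <- rep_len(as.numeric(mean_speed), n_subjects)
  mass <- rep_len(as.numeric(mass), n_subjects)
  if (rr_baseline <= 0.3) stop_config("rr_baseline must exceed 0.3 s")
  if (artifact_rate < 0 || artifact_rate >= 0.5) {
    stop_config("artifact_rate must lie in [0, 0.5)")
  }
  if (cadence <= 0) stop_config("cadence must be positive")
  if (rof_start < 1 || rof_end > 10 || rof_end < rof_start) {
    stop_config("ROF values must be non-decreasing within 1..10")
  }
  if (!is.null(slope_sections)) {
    slope_sections <- as.matrix(slope_sections)
    if (ncol(slope_sections) != 3L) {
      stop_config("slope_sections needs columns start_m, length_m, grade_pct")
    }
    o <- order(slope_sections[, 1L])
    slope_sections <- slope_sections[o, , drop = FALSE]
    ends <- slope_sections[, 1L] + slope_sections[, 2L]
    if (NROW(slope_sections) > 1L &&
        any(slope_sections[-1L, 1L] < ends[-length(ends)])) {
      stop_config("slope_sections must not overlap")
    }
  }
  ## fast/slow per the <90 min / >105 min thresholds
  group <- rep("mid", n_subjects)
  group[race_duration < 90 * 60] <- "fast"
  group[race_duration > 105 * 60] <- "slow"

  structure(list(
    n_subjects = n_subjects, race_duration = race_duration,
    mean_speed = mean_speed, group_label = group,
    rr_baseline = rr_baseline, rr_drift_slope = rr_drift_slope,
    hurst_alpha_target = hurst_alpha_target, lf_amp = lf_amp,
    hf_amp = hf_amp, rr_noise_sd = rr_noise_sd,
    artifact_rate = artifact_rate, cadence = cadence,
    trends = trends, trend_noise_sd = trend_noise_sd,
    baselines = baselines, mass = mass,
    slope_sections = slope_sections,
    rof_start = as.integer(rof_start), rof_end = as.integer(rof_end),
    rof_interval_s = rof_interval_s, sync_lag = sync_lag,
    ecg_fs = ecg_fs, imu_fs_chest = imu_fs_chest,
    imu_fs_foot = imu_fs_foot, gnss_fs = gnss_fs,
    ecg_snr_db = ecg_snr_db, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d subjects, race %.0f-%.0f min, seed %d\n",
              x$n_subjects, min(x$race_duration) / 60,
              max(x$race_duration) / 60, x$seed))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(table(x$group_label)),
                            table(x$group_label)), collapse = ", ")))
  invisible(x)
}
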