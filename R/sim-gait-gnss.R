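## Gait, GNSS and ROF generators.

#' Inertial stream container
#'
#' @param time uniform time vector (s).
#' @param acc n x 3 accelerometer matrix (m/s^2), columns AP, SI, ML.
#' @param gyro n x 3 gyroscope matrix (deg/s), columns sagittal, frontal,
#'   transverse.
#' @param fs sampling rate (Hz).
#' @return object of class `imu_stream`.
#' @export
imu_stream <- function(time, acc, gyro, fs) {
  if (fs <= 0) stop_config("fs must be positive")
  structure(list(time = as.numeric(time), acc = acc, gyro = gyro, fs = fs),
            class = "imu_stream")
}

## Per-cycle parameter truth following configured linear trends + noise.
## frac: per-cycle race fraction in [0,1].
trended_param <- function(name, frac, cfg, n) {
  base <- cfg$baselines[[name]]
  dr <- if (!is.null(cfg$trends[[name]])) cfg$trends[[name]] else 0
  nz <- if (!is.null(cfg$trend_noise_sd[[name]])) cfg$trend_noise_sd[[name]] else 0
  base * (1 + dr * frac) + base * nz * stats::rnorm(n)
}

#' Generate a subject's gait recording
#'
#' Produces the per-gait-cycle ground-truth parameter table (temporal
#' parameters, foot kinematics, trunk-acceleration ratios, speed) following
#' the configured linear fatigue trends plus white noise, and optionally the
#' raw foot and chest inertial streams built around those cycles: the foot
#' sagittal gyroscope carries one dominant positive peak per cycle at
#' mid-swing, and the chest accelerometer AP/ML channels have means
#' `a_AP * v` and `a_ML * v`. A sharp vertical "shock" spike is placed near
#' the start of both streams (the foot stream delayed by the configured
#' clock lag) for synchronization testing.
#'
#' @param cfg a [sim_config()].
#' @param subject subject index.
#' @param synth_imu logical; also synthesize the raw inertial streams
#'   (costly for long races; the cycle table alone feeds most analyses).
#' @return list with `cycles` (data.frame, one row per right-foot gait
#'   cycle), `foot`, `chest` ([imu_stream()] or NULL) and `truth` (events
#'   and the shock/sync metadata).
#' @export
generate_gait_recording <- function(cfg, subject = 1L, synth_imu = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  duration <- cfg$race_duration[subject]
  if (duration <= 0 || cfg$cadence <= 0) {
    stop_config("duration and cadence must be positive")
  }
  tg0 <- 60 / cfg$cadence
  n_cyc <- floor(duration / tg0)
  out <- with_seed(substream_seed(cfg$seed, subject, 23L), {
    frac <- (seq_len(n_cyc) - 0.5) / n_cyc
    cad_dr <- if (!is.null(cfg$trends$cadence)) cfg$trends$cadence else 0
    cad_nz <- if (!is.null(cfg$trend_noise_sd$cadence)) cfg$trend_noise_sd$cadence else 0
    t_g <- tg0 / (1 + cad_dr * frac) * (1 + cad_nz * stats::rnorm(n_cyc))
    ## trim cycles so the race duration is conserved within one cycle
    cum <- cumsum(t_g)
    keep <- cum <= duration + t_g[1L]
    t_g <- t_g[keep]; frac <- frac[keep]; n <- length(t_g)
    start <- c(0, cum[keep])[seq_len(n)]
    t_c <- trended_param("t_c", frac, cfg, n)
    if (any(t_c <= 0)) stop_config("configured trend yields non-positive t_c")
    t_f <- pmax(0.01, trended_param("t_f", frac, cfg, n))
    v_dr <- if (!is.null(cfg$trends$v)) cfg$trends$v else 0
    v_nz <- if (!is.null(cfg$trend_noise_sd$v)) cfg$trend_noise_sd$v else 0
    v <- cfg$mean_speed[subject] * (1 + v_dr * frac) *
      (1 + v_nz * stats::rnorm(n))
    cycles <- data.frame(
      cycle_index = seq_len(n), side = "right",
      start_time = start, t_g = t_g, t_c = t_c, t_f = t_f,
      t_s = t_g - t_c, cadence = 60 / t_g,
      D_f = t_c / t_g,
      FSA = trended_param("FSA", frac, cfg, n),
      FEA = trended_param("FEA", frac, cfg, n),
      omega_s = trended_param("omega_s", frac, cfg, n),
      v = v,
      a_AP = trended_param("a_AP", frac, cfg, n),
      a_ML = trended_param("a_ML", frac, cfg, n)
    )
    cycles$k_vert <- vertical_stiffness(cycles$t_c, cycles$t_f,
                                        cfg$mass[subject])
    ## gait events: mid-swing at cycle starts; IC/TO inside each cycle
    ic <- start + 0.35 * t_g
    to <- ic + t_c
    list(cycles = cycles, ic = ic, to = to, midswing = c(start, start[n] + t_g[n]))
  })
  cycles <- out$cycles
  truth <- list(midswing = out$midswing, initial_contact = out$ic,
                toe_off = out$to, sync_lag = cfg$sync_lag,
                shock_time = 2.0)
  foot <- chest <- NULL
  if (synth_imu) {
    foot <- with_seed(substream_seed(cfg$seed, subject, 29L),
                      synth_foot_imu(cycles, out$midswing, cfg, truth))
    chest <- with_seed(substream_seed(cfg$seed, subject, 31L),
                       synth_chest_imu(cycles, cfg, truth, subject))
  }
  list(cycles = cycles, foot = foot, chest = chest, truth = truth)
}

## Foot IMU: sagittal gyro = baseline noise + positive gaussian peak at each
## mid-swing (amplitude from the cycle's omega_s); SI acc carries the shock.
## The foot clock runs `sync_lag` late: event at true time t appears at
## stream time t + sync_lag.
synth_foot_imu <- function(cycles, midswing, cfg, truth) {
  fs <- cfg$imu_fs_foot
  t_end <- max(midswing) + cfg$sync_lag + 1
  pre <- 4  # seconds of pre-race signal holding the shock
  n <- ceiling((t_end + pre) * fs)
  time <- (seq_len(n) - 1L) / fs
  gy_sag <- stats::rnorm(n, sd = 10)
  w <- 0.05
  ## mid-swing peaks: amplitude = omega_s of the cycle starting there
  amp <- c(cycles$omega_s, cycles$omega_s[nrow(cycles)])
  for (i in seq_along(midswing)) {
    tc <- midswing[i] + cfg$sync_lag + pre
    i0 <- max(1L, floor((tc - 4 * w) * fs)); i1 <- min(n, ceiling((tc + 4 * w) * fs))
    idx <- i0:i1
    gy_sag[idx] <- gy_sag[idx] + amp[i] * exp(-(time[idx] - tc)^2 / (2 * w^2))
  }
  acc_si <- stats::rnorm(n, sd = 0.5)
  acc_si <- acc_si + shock_pulse(time, truth$shock_time + cfg$sync_lag + pre, fs)
  acc <- cbind(AP = stats::rnorm(n, sd = 0.5), SI = acc_si,
               ML = stats::rnorm(n, sd = 0.5))
  gyro <- cbind(sagittal = gy_sag, frontal = stats::rnorm(n, sd = 10),
                transverse = stats::rnorm(n, sd = 10))
  st <- imu_stream(time, acc, gyro, fs)
  st$race_offset <- pre + cfg$sync_lag  # stream time of race t = 0
  st
}

## Chest IMU: AP/ML accelerations with configured speed-normalised means,
## step-frequency oscillation, SI channel with impacts + shock pulse.
synth_chest_imu <- function(cycles, cfg, truth, subject) {
  fs <- cfg$imu_fs_chest
  t_end <- max(cycles$start_time + cycles$t_g)
  pre <- 4
  n <- ceiling((t_end + pre) * fs)
  time <- (seq_len(n) - 1L) / fs
  race_t <- time - pre
  ## piecewise-constant per-cycle values sampled at the stream rate
  idx <- findInterval(race_t, cycles$start_time)
  idx[idx < 1L] <- 1L; idx[idx > nrow(cycles)] <- nrow(cycles)
  f_step <- 2 * cycles$cadence[idx] / 60  # two steps per stride
  ap_mean <- cycles$a_AP[idx] * cycles$v[idx]
  ml_mean <- cycles$a_ML[idx] * cycles$v[idx]
  phase <- 2 * pi * cumsum(f_step) / fs
  acc_ap <- ap_mean + 0.3 * ap_mean * sin(phase) + stats::rnorm(n, sd = 0.05)
  acc_ml <- ml_mean + 0.3 * ml_mean * sin(phase / 2) + stats::rnorm(n, sd = 0.05)
  acc_si <- 2 * sin(phase) + stats::rnorm(n, sd = 0.2) +
    shock_pulse(time, truth$shock_time + pre, fs)
  acc <- cbind(AP = acc_ap, SI = acc_si, ML = acc_ml)
  gyro <- cbind(sagittal = stats::rnorm(n, sd = 5),
                frontal = stats::rnorm(n, sd = 5),
                transverse = stats::rnorm(n, sd = 5))
  st <- imu_stream(time, acc, gyro, fs)
  st$race_offset <- pre
  st
}

## One sharp asymmetric up-down pulse (~80 ms) standing far above the
## locomotor band, used as the cross-correlation synchronization landmark.
shock_pulse <- function(time, t0, fs) {
  s <- 0.012
  50 * (-(time - t0) / s) * exp(-(time - t0)^2 / (2 * s^2)) *
    (abs(time - t0) < 0.2)
}

#' Generate a subject's GNSS track
#'
#' Positions follow a straight northward path in local metres converted to
#' latitude/longitude on a sphere; the elevation profile integrates the
#' configured grade sections (constant grade over each section, flat
#' elsewhere). The speed channel is the configured profile.
#'
#' @param cfg a [sim_config()].
#' @param subject subject index.
#' @param speed optional speed profile (m/s) sampled at the GNSS rate;
#'   defaults to the subject's constant mean speed.
#' @return object of class `gnss_track`: data.frame(time, lat, lon, ele,
#'   speed) with attributes `fs` and `slope_truth` (true section intervals
#'   in metres and seconds).
#' @export
generate_gnss_track <- function(cfg, subject = 1L, speed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$gnss_fs
  duration <- cfg$race_duration[subject]
  n <- floor(duration * fs) + 1L
  time <- (seq_len(n) - 1L) / fs
  if (is.null(speed)) speed <- rep(cfg$mean_speed[subject], n)
  speed <- rep_len(speed, n)
  if (all(speed == 0)) stop_config("degenerate track: speed profile is all zero")
  dist <- c(0, cumsum(speed[-n] / fs))
  secs <- cfg$slope_sections
  if (!is.null(secs) && NROW(secs) > 0L &&
      any(secs[, 1L] + secs[, 2L] > max(dist) + 1e-9)) {
    stop_config("slope_sections extend beyond the race length")
  }
  ele <- numeric(n)
  slope_truth <- NULL
  if (!is.null(secs) && NROW(secs) > 0L) {
    grad <- numeric(n)
    for (i in seq_len(NROW(secs))) {
      s0 <- secs[i, 1L]; s1 <- secs[i, 1L] + secs[i, 2L]
      grad[dist >= s0 & dist < s1] <- secs[i, 3L] / 100
    }
    ele <- c(0, cumsum(grad[-n] * diff(dist)))
    t0 <- vapply(secs[, 1L], function(s) time[which(dist >= s)[1L]], 0)
    t1 <- vapply(secs[, 1L] + secs[, 2L],
                 function(s) time[which(dist >= s)[1L]], 0)
    slope_truth <- cbind(start_s = t0, end_s = t1,
                         start_m = secs[, 1L],
                         end_m = secs[, 1L] + secs[, 2L])
  }
  lat0 <- 46.5
  lat <- lat0 + dist / (pi * 6371000 / 180)
  track <- data.frame(time = time, lat = lat, lon = 6.6, ele = ele,
                      speed = speed)
  attr(track, "fs") <- fs
  attr(track, "slope_truth") <- slope_truth
  class(track) <- c("gnss_track", "data.frame")
  track
}

#' Generate a subject's rating-of-fatigue log
#'
#' One prompt per `rof_interval_s` (10 min in the emulated protocol). Values
#' follow a non-decreasing integer trajectory from `rof_start` to `rof_end`
#' (linear in prompt index, rounded). Warns when some race segment would
#' receive no prompt.
#'
#' @param cfg a [sim_config()].
#' @param subject subject index.
#' @param trajectory optional explicit non-decreasing integer vector, one
#'   value per prompt.
#' @return data.frame(time, rof).
#' @export
generate_rof_schedule <- function(cfg, subject = 1L, trajectory = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  duration <- cfg$race_duration[subject]
  times <- seq(cfg$rof_interval_s, duration, by = cfg$rof_interval_s)
  k <- length(times)
  if (is.null(trajectory)) {
    trajectory <- round(seq(cfg$rof_start, cfg$rof_end, length.out = k))
  }
  trajectory <- rep_len(as.integer(trajectory), k)
  if (any(trajectory < 1L | trajectory > 10L)) {
    stop_config("ROF values must lie in 1..10")
  }
  if (is.unsorted(trajectory)) {
    stop_config("ROF trajectory must be non-decreasing")
  }
  ## one-per-segment check (clamping the final prompt into segment 8)
  seg <- pmin(8L, 1L + floor(times / duration * 8))
  if (length(unique(seg)) < 8L) {
    warning("some race segments receive no ROF prompt", call. = FALSE)
  }
  data.frame(time = times, rof = trajectory)
}

#' Simulate one subject's full race recording
#'
#' @param cfg a [sim_config()].
#' @param subject subject index.
#' @param signals character subset of c("rr", "ecg", "gait", "imu", "gnss",
#'   "rof"); "imu" implies "gait" and additionally synthesizes raw inertial
#'   streams.
#' @return list with the requested components plus `truth` and bookkeeping
#'   (`subject`, `group`, `race_duration`, `mass`).
#' @export
simulate_subject <- function(cfg, subject = 1L,
                             signals = c("rr", "gait", "gnss", "rof")) {
  out <- list(subject = subject, group = cfg$group_label[subject],
              race_duration = cfg$race_duration[subject],
              mass = cfg$mass[subject], truth = list())
  if ("rr" %in% signals || "ecg" %in% signals) {
    g <- generate_rr_series(cfg, subject)
    out$rr <- g$rr
    out$truth$beat_times <- g$truth$beat_times
    if (cfg$artifact_rate > 0) {
      inj <- inject_rr_artifacts(g$rr, cfg$artifact_rate,
                                 substream_seed(cfg$seed, subject, 37L))
      out$rr_corrupted <- inj$rr
      out$truth$injected_artifact_indices <- inj$indices
    }
    if ("ecg" %in% signals) {
      out$ecg <- synthesize_ecg(g$rr, cfg$ecg_fs, cfg$ecg_snr_db,
                                substream_seed(cfg$seed, subject, 41L))
    }
  }
  if ("gait" %in% signals || "imu" %in% signals) {
    g <- generate_gait_recording(cfg, subject, synth_imu = "imu" %in% signals)
    out$cycles <- g$cycles
    out$foot <- g$foot
    out$chest <- g$chest
    out$truth <- c(out$truth, g$truth)
  }
  if ("gnss" %in% signals) {
    out$gnss <- generate_gnss_track(cfg, subject)
    out$truth$slope_sections <- attr(out$gnss, "slope_truth")
  }
  if ("rof" %in% signals) {
    out$rof <- generate_rof_schedule(cfg, subject)
    out$truth$rof <- out$rof
  }
  out
}

#' Simulate the whole cohort
#'
#' @param cfg a [sim_config()].
#' @inheritParams simulate_subject
#' @return list of per-subject recordings (see [simulate_subject()]).
#' @export
simulate_cohort <- function(cfg, signals = c("rr", "gait", "gnss", "rof")) {
  lapply(seq_len(cfg$n_subjects), function(s)
    simulate_subject(cfg, s, signals))
}
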