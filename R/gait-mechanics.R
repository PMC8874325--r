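## Per-gait-cycle biomechanics: cycle segmentation, temporal parameters,
## duty factor, spring-mass vertical stiffness, trunk-acceleration ratios.

#' Segment gait cycles at mid-swing from the foot gyroscope
#'
#' Mid-swing shows as the dominant positive peak of the sagittal angular
#' velocity; consecutive peak pairs delimit one gait cycle.
#'
#' @param foot an [imu_stream()] with a "sagittal" gyro column.
#' @param min_prominence minimum peak height (deg/s).
#' @param min_separation minimum peak spacing (s).
#' @return numeric vector of mid-swing times (cycle boundaries); fewer than
#'   2 peaks yields no cycles.
#' @export
segment_cycles_midswing <- function(foot, min_prominence = 100,
                                    min_separation = 0.4) {
  g <- foot$gyro[, "sagittal"]
  pk <- pracma::findpeaks(g, minpeakheight = min_prominence,
                          minpeakdistance = max(1L, round(min_separation * foot$fs)))
  if (is.null(pk) || nrow(pk) < 2L) return(numeric(0))
  sort(foot$time[pk[, 2L]])
}

#' Drop the first and last n steps
#'
#' Transient-effect trimming at race boundaries.
#'
#' @param cycles a gait-cycle data.frame (one row per cycle).
#' @param n number of cycles trimmed from each end.
#' @return the trimmed data.frame (possibly 0 rows, with a warning).
#' @export
trim_steps <- function(cycles, n = 10) {
  m <- nrow(cycles)
  if (m <= 2 * n) {
    warning("fewer cycles than twice the trim length; nothing retained",
            call. = FALSE)
    return(cycles[0, , drop = FALSE])
  }
  cycles[(n + 1L):(m - n), , drop = FALSE]
}

#' Duty factor
#'
#' Ratio of contact time to stride (cycle) time.
#'
#' @param t_c contact time (s).
#' @param t_g cycle time (s), > 0.
#' @return D_f, with an `invalid` attribute flagging cycles where
#'   `t_c > t_g`.
#' @export
duty_factor <- function(t_c, t_g) {
  if (any(t_g <= 0)) stop_config("t_g must be positive")
  d <- t_c / t_g
  attr(d, "invalid") <- t_c > t_g
  d
}

#' Spring-mass vertical stiffness
#'
#' Sine-wave ground-reaction-force spring-mass model: the peak vertical
#' force and centre-of-mass displacement during contact follow from contact
#' and flight times alone,
#' \deqn{F_{max} = m g \frac{\pi}{2}\left(\frac{t_f}{t_c} + 1\right)}
#' \deqn{\Delta z = \frac{F_{max} t_c^2}{m \pi^2} - \frac{g t_c^2}{8}}
#' and `k_vert = F_max / dz`, reported in kN/m.
#'
#' @param t_c contact time (s), > 0.
#' @param t_f flight time (s), >= 0.
#' @param mass body mass (kg), > 0.
#' @param g gravitational acceleration (m/s^2).
#' @return vertical stiffness in kN/m; NA where the displacement is
#'   non-positive.
#' @export
vertical_stiffness <- function(t_c, t_f, mass, g = 9.81) {
  if (any(t_c <= 0) || any(t_f < 0) || any(mass <= 0)) {
    stop_config("t_c and mass must be positive, t_f non-negative")
  }
  f_max <- mass * g * (pi / 2) * (t_f / t_c + 1)
  dz <- f_max * t_c^2 / (mass * pi^2) - g * t_c^2 / 8
  ifelse(dz > 0, f_max / dz / 1000, NA_real_)
}

#' Speed-normalised trunk acceleration ratios
#'
#' Rectified means of the chest anterior-posterior and medio-lateral
#' accelerations divided by the mean running speed over each window
#' (normalisation isolates the fatigue response from speed changes).
#'
#' @param chest an [imu_stream()] with "AP" and "ML" accelerometer columns.
#' @param speed data.frame(time, speed) in m/s.
#' @param windows matrix/data.frame of half-open `[start, end)` windows (s);
#'   default one window over the whole stream.
#' @param rectify take `mean(|a|)` (default) rather than `mean(a)`.
#' @return data.frame(start, end, a_AP, a_ML); NA where mean speed is not
#'   positive.
#' @export
trunk_ratios <- function(chest, speed, windows = NULL, rectify = TRUE) {
  if (is.null(windows)) {
    windows <- cbind(min(chest$time), max(chest$time) + 1e-9)
  }
  windows <- as.matrix(windows)
  f <- if (rectify) function(a) mean(abs(a)) else mean
  out <- lapply(seq_len(nrow(windows)), function(w) {
    sel <- chest$time >= windows[w, 1L] & chest$time < windows[w, 2L]
    vs <- speed$speed[speed$time >= windows[w, 1L] &
                        speed$time < windows[w, 2L]]
    v <- if (length(vs)) mean(vs) else NA_real_
    if (!is.finite(v) || v <= 0 || !any(sel)) {
      data.frame(start = windows[w, 1L], end = windows[w, 2L],
                 a_AP = NA_real_, a_ML = NA_real_)
    } else {
      data.frame(start = windows[w, 1L], end = windows[w, 2L],
                 a_AP = f(chest$acc[sel, "AP"]) / v,
                 a_ML = f(chest$acc[sel, "ML"]) / v)
    }
  })
  do.call(rbind, out)
}

#' Temporal gait parameters from per-cycle events
#'
#' For each cycle delimited by consecutive mid-swings: contact time from
#' initial contact to toe-off, flight time from toe-off to the next initial
#' contact under the configured step convention, cycle time mid-swing to
#' mid-swing, swing time as their complement, and cadence in strides/min.
#'
#' @param midswing cycle boundary times (n+1 values for n cycles).
#' @param initial_contact,toe_off per-cycle event times (n values, NA for a
#'   missing event).
#' @return data.frame(cycle_index, t_c, t_f, t_s, t_g, cadence, valid);
#'   cycles with missing or non-positive durations are flagged invalid.
#' @export
temporal_params <- function(midswing, initial_contact, toe_off) {
  n <- length(midswing) - 1L
  if (n < 1L) stop_config("need at least two mid-swing events")
  stopifnot(length(initial_contact) == n, length(toe_off) == n)
  t_g <- diff(midswing)
  t_c <- toe_off - initial_contact
  next_ic <- c(initial_contact[-1L], NA_real_)
  t_f <- next_ic - toe_off
  t_s <- t_g - t_c
  valid <- is.finite(t_c) & is.finite(t_g) & t_c > 0 & t_g > 0 & t_c < t_g
  data.frame(cycle_index = seq_len(n), t_c = t_c, t_f = t_f, t_s = t_s,
             t_g = t_g, cadence = 60 / t_g, valid = valid)
}

#' Build the per-cycle gait table from raw inertial streams
#'
#' Detects mid-swing cycle boundaries on the foot gyroscope, derives
#' temporal parameters from the supplied (or truth-provided) contact
#' events, computes duty factor and spring-mass stiffness, attaches
#' speed-normalised trunk ratios per cycle window, merges optional
#' externally-computed kinematic columns (FSA, FEA, omega_s as per-cycle
#' pass-through values), and trims the first and last `trim` steps.
#'
#' @param foot,chest [imu_stream()] objects (race-time clocks).
#' @param events list with `initial_contact` and `toe_off` times (per
#'   cycle), e.g. from generator truth or a threshold detector.
#' @param speed data.frame(time, speed).
#' @param mass body mass (kg).
#' @param kinematics optional data.frame(cycle_index, FSA, FEA, omega_s).
#' @param trim steps trimmed at each end.
#' @return gait-cycle data.frame.
#' @export
gait_cycle_table <- function(foot, chest, events, speed, mass,
                             kinematics = NULL, trim = 10) {
  ms <- segment_cycles_midswing(foot)
  if (length(ms) < 2L) stop_config("no gait cycles detected")
  n <- length(ms) - 1L
  ic <- rep(NA_real_, n); to <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- events$initial_contact >= ms[i] & events$initial_contact < ms[i + 1L]
    if (any(sel)) {
      ic[i] <- events$initial_contact[sel][1L]
      j <- which(events$toe_off > ic[i])[1L]
      if (!is.na(j)) to[i] <- events$toe_off[j]
    }
  }
  tp <- temporal_params(ms, ic, to)
  tp$start_time <- ms[-length(ms)]
  tp$side <- "right"
  tp$D_f <- duty_factor(tp$t_c, tp$t_g)
  ## sanitize before the vectorised call: NA events would trip its checks
  tf0 <- ifelse(is.finite(tp$t_f), pmax(tp$t_f, 0), 0)
  tc0 <- ifelse(is.finite(tp$t_c), pmax(tp$t_c, 1e-6), 1e-6)
  tp$k_vert <- ifelse(tp$valid & is.finite(tp$t_f) & tp$t_f >= 0,
                      vertical_stiffness(tc0, tf0, mass),
                      NA_real_)
  tr <- trunk_ratios(chest, speed, cbind(ms[-length(ms)], ms[-1L]))
  tp$a_AP <- tr$a_AP
  tp$a_ML <- tr$a_ML
  vsel <- vapply(seq_len(n), function(i) {
    vs <- speed$speed[speed$time >= ms[i] & speed$time < ms[i + 1L]]
    if (length(vs)) mean(vs) else NA_real_
  }, 0)
  tp$v <- vsel
  if (!is.null(kinematics)) {
    for (col in intersect(c("FSA", "FEA", "omega_s"), names(kinematics))) {
      tp[[col]] <- kinematics[[col]][match(tp$cycle_index,
                                           kinematics$cycle_index)]
    }
  }
  trim_steps(tp, trim)
}
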