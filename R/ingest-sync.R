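## Sensor synchronization, course geometry and exclusion logic.

#' Estimate the clock lag between two inertial streams
#'
#' Cross-correlates the vertical (SI) acceleration of two streams around the
#' shared "shock" synchronization movement: both channels are linearly
#' resampled to the higher of the two sampling rates, mean-removed, and the
#' lag maximising the normalized cross-correlation within
#' `+/- search_window` is returned. Adding the returned lag to stream `b`'s
#' clock aligns the shock peaks (positive lag = `b` runs late).
#'
#' @param acc_a,acc_b [imu_stream()] objects containing the shock event.
#' @param search_window maximum absolute lag searched, seconds.
#' @param min_peak minimum acceptable normalized correlation peak; below it
#'   the synchronization is ambiguous and an error is raised.
#' @return lag in seconds.
#' @export
estimate_lag <- function(acc_a, acc_b, search_window = 5, min_peak = 0.5) {
  fs <- max(acc_a$fs, acc_b$fs)
  t0 <- max(min(acc_a$time), min(acc_b$time))
  t1 <- min(max(acc_a$time), max(acc_b$time))
  if (t1 - t0 <= 2 / fs) stop_config("streams do not overlap")
  tt <- seq(t0, t1, by = 1 / fs)
  xa <- stats::approx(acc_a$time, acc_a$acc[, "SI"], xout = tt)$y
  xb <- stats::approx(acc_b$time, acc_b$acc[, "SI"], xout = tt)$y
  xa <- xa - mean(xa); xb <- xb - mean(xb)
  max_lag <- min(length(tt) - 1L, round(search_window * fs))
  cc <- stats::ccf(xa, xb, lag.max = max_lag, plot = FALSE,
                   type = "correlation")
  i <- which.max(cc$acf)
  if (cc$acf[i] < min_peak) {
    stop_config("ambiguous synchronization: correlation peak %.2f < %.2f",
                cc$acf[i], min_peak)
  }
  ## ccf lag k maximal where xa[t] ~ xb[t+k]: b leads a by k samples, so b's
  ## clock must be advanced by -k/fs... sign convention: b delayed by tau
  ## gives peak at k = -tau*fs, hence lag = -k/fs.
  -cc$lag[i] / fs
}

#' Great-circle (Haversine) distance
#'
#' Spherical-earth distance with radius 6,371,000 m.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorised).
#' @return distance in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop_config("coordinates out of range")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

#' Detect sloped course sections from a GNSS track
#'
#' Computes cumulative Haversine distance along the track and, for every
#' fix, the mean grade over the following `window` metres; runs of fixes
#' whose absolute grade strictly exceeds `grade_threshold` percent are
#' merged into half-open exclusion intervals in track time. A hair of
#' relative tolerance (1e-9) guards the strict comparison against
#' floating-point noise, so an exactly-threshold grade is not flagged.
#'
#' @param track a [generate_gnss_track()] result or any data.frame with
#'   columns time, lat, lon, ele.
#' @param grade_threshold grade threshold in percent (strict inequality).
#' @param window distance window in metres.
#' @return object of class `exclusion_mask`: data.frame(start, end, reason).
#' @export
detect_slopes <- function(track, grade_threshold = 5, window = 100) {
  n <- nrow(track)
  dist <- c(0, cumsum(haversine_m(track$lat[-n], track$lon[-n],
                                  track$lat[-1L], track$lon[-1L])))
  if (max(dist) < window) {
    warning("track shorter than the grade window; no slopes detectable",
            call. = FALSE)
    return(exclusion_mask(numeric(0), numeric(0), character(0)))
  }
  j <- findInterval(dist + window, dist, left.open = FALSE)
  j[j > n] <- n
  valid <- which(dist[j] - dist > window / 2)  # windows with real extent
  grade <- abs(track$ele[j[valid]] - track$ele[valid]) /
    (dist[j[valid]] - dist[valid]) * 100
  flag <- grade > grade_threshold * (1 + 1e-9)
  if (!any(flag)) return(exclusion_mask(numeric(0), numeric(0), character(0)))
  iv <- cbind(track$time[valid[flag]], track$time[j[valid[flag]]])
  iv <- merge_intervals(iv)
  exclusion_mask(iv[, 1L], iv[, 2L], rep("slope", nrow(iv)))
}

#' Exclusion mask constructor
#'
#' @param start,end interval bounds in seconds (half-open `[start, end)`).
#' @param reason character label per interval ("slope" or "transient").
#' @return sorted, disjoint mask of class `exclusion_mask`.
#' @export
exclusion_mask <- function(start, end, reason = rep("slope", length(start))) {
  m <- data.frame(start = as.numeric(start), end = as.numeric(end),
                  reason = as.character(reason))
  m <- m[order(m$start), , drop = FALSE]
  if (nrow(m) > 1L && any(m$start[-1L] < m$end[-nrow(m)])) {
    stop_config("exclusion intervals must be disjoint")
  }
  rownames(m) <- NULL
  class(m) <- c("exclusion_mask", "data.frame")
  m
}

#' Drop rows falling inside excluded intervals
#'
#' @param series data.frame with a `time` column (seconds).
#' @param mask an [exclusion_mask()].
#' @param time_col name of the time column.
#' @return the filtered data.frame, ordering preserved.
#' @export
exclude_intervals <- function(series, mask, time_col = "time") {
  if (is.null(mask) || nrow(mask) == 0L) return(series)
  keep <- !in_intervals(series[[time_col]], as.matrix(mask[, c("start", "end")]))
  series[keep, , drop = FALSE]
}

#' Replace 2-SD outliers by linear interpolation, per segment window
#'
#' Within each window, samples deviating from the window mean by more than
#' `k` window standard deviations are replaced by linear interpolation
#' between the nearest retained neighbours (nearest retained value at the
#' edges). A constant window (SD = 0) is returned untouched.
#'
#' @param x numeric signal.
#' @param t sample times (defaults to the index).
#' @param windows matrix/data.frame of half-open `[start, end)` intervals in
#'   `t` units; default one window spanning the whole signal.
#' @param k SD multiplier.
#' @return numeric vector with outliers replaced.
#' @export
remove_outliers_2sd <- function(x, t = seq_along(x), windows = NULL, k = 2) {
  if (is.null(windows)) windows <- cbind(min(t), max(t) + 1e-9)
  windows <- as.matrix(windows)
  out <- x
  for (w in seq_len(nrow(windows))) {
    idx <- which(t >= windows[w, 1L] & t < windows[w, 2L])
    if (length(idx) < 3L) next
    xi <- x[idx]
    s <- sd0(xi)
    if (s == 0) next
    bad <- abs(xi - mean(xi)) > k * s
    if (!any(bad) || all(bad)) next
    good <- which(!bad)
    repl <- stats::approx(good, xi[good], xout = which(bad), rule = 2)$y
    xi[bad] <- repl
    out[idx] <- xi
  }
  out
}

#' Segment a recording into activity periods
#'
#' With explicit annotations (a data.frame of label/start/end) the intervals
#' pass through after validation. Without annotations a heuristic flags
#' activity from the moving variance of the acceleration norm: the longest
#' high-energy bout is labelled `race`.
#'
#' @param annotations data.frame(label, start, end) or NULL.
#' @param imu an [imu_stream()], required for heuristic mode.
#' @param var_window window (s) for the moving variance.
#' @param var_threshold activity threshold as a fraction of the maximum
#'   moving variance.
#' @return data.frame(label, start, end); a `race` interval is guaranteed.
#' @export
segment_activities <- function(annotations = NULL, imu = NULL,
                               var_window = 5, var_threshold = 0.1) {
  if (!is.null(annotations)) {
    stopifnot(all(c("label", "start", "end") %in% names(annotations)))
    if (!"race" %in% annotations$label) {
      stop_config("annotations contain no race interval")
    }
    return(annotations)
  }
  if (is.null(imu)) stop_config("need annotations or an inertial stream")
  norm <- sqrt(rowSums(imu$acc^2))
  n <- round(var_window * imu$fs)
  mu <- moving_avg(norm, n)
  v <- moving_avg((norm - mu)^2, n)
  active <- v > var_threshold * max(v)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  runs <- which(r$values)
  if (length(runs) == 0L) stop_config("no activity found; race interval missing")
  best <- runs[which.max(r$lengths[runs])]
  data.frame(label = "race",
             start = imu$time[starts[best]],
             end = imu$time[ends[best]])
}
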