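## Eight-segment race splitting, aggregation, normalization and ROF labels.

#' Split a race interval into equal segments
#'
#' Time-based by default (ROF prompts are clocked in time); distance-based
#' splitting is available when a GNSS track is supplied.
#'
#' @param race_start,race_end race interval bounds (s).
#' @param n number of segments (>= 2).
#' @param track optional [generate_gnss_track()] result; when given,
#'   boundaries are placed at equal cumulative-distance fractions.
#' @return data.frame(segment, start, end) of half-open intervals
#'   partitioning the race.
#' @export
split_race <- function(race_start, race_end, n = 8, track = NULL) {
  if (n < 2) stop_config("need at least 2 segments")
  if (race_end <= race_start) stop_config("empty race interval")
  if (is.null(track)) {
    b <- seq(race_start, race_end, length.out = n + 1L)
  } else {
    m <- nrow(track)
    dist <- c(0, cumsum(haversine_m(track$lat[-m], track$lon[-m],
                                    track$lat[-1L], track$lon[-1L])))
    targets <- seq(0, max(dist), length.out = n + 1L)
    b <- stats::approx(dist, track$time, xout = targets, ties = "ordered")$y
    b[1L] <- race_start; b[n + 1L] <- race_end
  }
  data.frame(segment = seq_len(n), start = b[-(n + 1L)], end = b[-1L])
}

## Segment id per time, half-open, with the race end clamped into the last
## segment so the final sample/prompt is not orphaned.
segment_of <- function(t, segments) {
  s <- findInterval(t, c(segments$start, segments$end[nrow(segments)]),
                    left.open = FALSE)
  s[s > nrow(segments) | (s == nrow(segments) + 1L)] <- nrow(segments)
  s[t < segments$start[1L] | t > segments$end[nrow(segments)]] <- NA_integer_
  s
}

#' Aggregate a parameter stream per race segment
#'
#' Median and interquartile range (linear-interpolation quantiles) of the
#' samples falling in each half-open segment; empty segments yield NA.
#'
#' @param t sample times (s).
#' @param x sample values.
#' @param segments a [split_race()] result.
#' @return data.frame(segment, median, iqr, n_samples).
#' @export
aggregate_segments <- function(t, x, segments) {
  seg <- segment_of(t, segments)
  out <- lapply(segments$segment, function(s) {
    xi <- x[!is.na(seg) & seg == s & is.finite(x)]
    data.frame(segment = s,
               median = if (length(xi)) stats::median(xi) else NA_real_,
               iqr = if (length(xi)) iqr_lin(xi) else NA_real_,
               n_samples = length(xi))
  })
  do.call(rbind, out)
}

#' Normalize segment medians against a reference segment
#'
#' Biomechanical parameters are referenced to the segment with the highest
#' median running speed; physiological parameters to the first segment (the
#' non-fatigued state).
#'
#' @param seg_median numeric vector of per-segment medians (index =
#'   segment).
#' @param mode "biomech" or "physio".
#' @param speed_median per-segment median speed, required for biomech mode.
#' @return list(normalized, reference) where `normalized` has the reference
#'   segment at exactly 1; a zero/missing reference median yields all-NA.
#' @export
normalize_segments <- function(seg_median, mode = c("physio", "biomech"),
                               speed_median = NULL) {
  mode <- match.arg(mode)
  ref <- if (mode == "biomech") {
    if (is.null(speed_median)) stop_config("biomech mode needs speed medians")
    which.max(speed_median)
  } else 1L
  den <- seg_median[ref]
  if (!is.finite(den) || den == 0) {
    return(list(normalized = rep(NA_real_, length(seg_median)),
                reference = ref))
  }
  list(normalized = seg_median / den, reference = ref)
}

## ΔROF pooling rule: 0, [1,2], [3,4], >= 5.
pool_delta_rof <- function(delta) {
  cut(delta, breaks = c(-Inf, 0.5, 2.5, 4.5, Inf),
      labels = c("0", "[1,2]", "[3,4]", ">=5"))
}

#' Attach ROF, delta-ROF states and L/M/H levels to race segments
#'
#' Per-segment ROF is the median of the prompts falling in the segment
#' (rounded half-up to an integer); delta-ROF subtracts the first-segment
#' baseline and is pooled into the four onset states 0, [1,2], [3,4] and
#' >= 5. L/M/H mark the segments attaining the subject's lowest, medium and
#' highest recorded ROF (medium = recorded value closest to the median of
#' the distinct recorded values, ties resolved to the lower value).
#'
#' @param rof_log data.frame(time, rof).
#' @param segments a [split_race()] result.
#' @return data.frame(segment, rof, delta_rof, delta_state, level); empty
#'   segments carry NA (with a warning).
#' @export
assign_rof <- function(rof_log, segments) {
  seg <- segment_of(rof_log$time, segments)
  rof <- vapply(segments$segment, function(s) {
    v <- rof_log$rof[!is.na(seg) & seg == s]
    if (!length(v)) return(NA_real_)
    floor(stats::median(v) + 0.5)
  }, 0)
  if (anyNA(rof)) warning("segments without any ROF prompt", call. = FALSE)
  delta <- rof - rof[1L]
  lvl <- rep(NA_character_, length(rof))
  vals <- sort(unique(rof[!is.na(rof)]))
  if (length(vals)) {
    lo <- min(vals); hi <- max(vals)
    med_t <- stats::median(vals)
    below <- abs(vals - med_t)
    mid <- vals[which(below == min(below))][1L]  # tie -> lower value
    lvl[rof == lo] <- "L"
    lvl[rof == mid] <- "M"
    lvl[rof == hi] <- "H"
    ## a single recorded value collapses the levels onto the same segments
    if (lo == hi) lvl[!is.na(rof)] <- "L=M=H"
  }
  data.frame(segment = segments$segment, rof = rof, delta_rof = delta,
             delta_state = pool_delta_rof(delta), level = lvl)
}

#' Build a subject's segment feature matrix
#'
#' Aggregates every parameter stream over the 8 race segments, normalizes
#' (biomech parameters against the fastest segment, physiological against
#' segment 1) and attaches the ROF assignment.
#'
#' @param streams named list of data.frame(time, value) parameter streams.
#' @param kinds named character vector mapping each parameter to "biomech"
#'   or "physio".
#' @param rof_log data.frame(time, rof).
#' @param race_start,race_end race interval (s).
#' @param n_segments number of segments.
#' @param speed_stream data.frame(time, value) of running speed used to pick
#'   the biomech reference segment (defaults to `streams$v`).
#' @return long data.frame(segment, parameter, kind, median, iqr,
#'   normalized, n_samples, rof, delta_rof, delta_state, level).
#' @export
segment_feature_matrix <- function(streams, kinds, rof_log, race_start,
                                   race_end, n_segments = 8,
                                   speed_stream = NULL) {
  segments <- split_race(race_start, race_end, n_segments)
  if (is.null(speed_stream)) speed_stream <- streams[["v"]]
  speed_med <- if (!is.null(speed_stream)) {
    aggregate_segments(speed_stream$time, speed_stream$value, segments)$median
  } else NULL
  rof <- assign_rof(rof_log, segments)
  out <- lapply(names(streams), function(p) {
    agg <- aggregate_segments(streams[[p]]$time, streams[[p]]$value, segments)
    kind <- unname(kinds[[p]])
    nm <- normalize_segments(agg$median, mode = kind,
                             speed_median = speed_med)
    data.frame(segment = agg$segment, parameter = p, kind = kind,
               median = agg$median, iqr = agg$iqr,
               normalized = nm$normalized, n_samples = agg$n_samples)
  })
  out <- do.call(rbind, out)
  merge(out, rof, by = "segment", sort = TRUE)
}
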