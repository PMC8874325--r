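## Heart-rate dynamics: QRS detection, RR correction, HRV/HRC metrics.

#' Rolling analysis windows
#'
#' Windows of `length` seconds starting at 0 and stepping by
#' `length - overlap` (default 120 s windows every 10 s); a trailing partial
#' window is dropped.
#'
#' @param duration total signal duration (s).
#' @param length window length (s).
#' @param overlap window overlap (s); must be < `length`.
#' @return data.frame(start, end, center), possibly 0 rows (with a warning).
#' @export
window_stream <- function(duration, length = 120, overlap = 110) {
  if (overlap >= length) stop_config("overlap must be smaller than length")
  step <- length - overlap
  if (duration < length) {
    warning("signal shorter than one window", call. = FALSE)
    return(data.frame(start = numeric(0), end = numeric(0),
                      center = numeric(0)))
  }
  starts <- seq(0, duration - length, by = step)
  data.frame(start = starts, end = starts + length,
             center = starts + length / 2)
}

#' Linearly resample an ECG stream
#'
#' @param ecg an `ecg_stream` (list with time, mv, fs).
#' @param fs_out output sampling rate (Hz), at least the input rate.
#' @return resampled `ecg_stream`.
#' @export
resample_linear <- function(ecg, fs_out = 1000) {
  if (fs_out < ecg$fs) stop_config("fs_out must be >= the input rate")
  if (length(ecg$time) == 0L) {
    return(structure(list(time = numeric(0), mv = numeric(0), fs = fs_out),
                     class = "ecg_stream"))
  }
  tt <- seq(min(ecg$time), max(ecg$time), by = 1 / fs_out)
  structure(list(time = tt,
                 mv = stats::approx(ecg$time, ecg$mv, xout = tt)$y,
                 fs = fs_out),
            class = "ecg_stream")
}

#' Energy-based QRS detection
#'
#' Non-linear filtering: a coefficient vector formed from the ratio of
#' short-term to long-term moving-average energies,
#' `c(t) = E_short(t) / (E_long(t) + eps)`, multiplies a lightly smoothed
#' version of the signal energy to heighten QRS peaks and suppress slow
#' perturbations. Peaks of the enhanced signal above an adaptive threshold
#' (median + 4 MAD; a fixed fraction of the maximum when the MAD
#' degenerates to zero on near-silent signals) separated by a refractory
#' period are reported; each beat time is refined to the local energy
#' maximum within +/- 20 ms.
#'
#' @param ecg an `ecg_stream`, ideally resampled to 1000 Hz.
#' @param short_s,long_s energy window lengths (s).
#' @param eps stabiliser in the energy ratio.
#' @param thresh_mads threshold in MAD units above the median of the
#'   enhanced signal.
#' @param refractory minimum beat separation (s).
#' @return numeric vector of beat times (s), possibly empty.
#' @export
detect_qrs <- function(ecg, short_s = 0.10, long_s = 1.0, eps = 1e-6,
                       thresh_mads = 4, refractory = 0.25) {
  x <- ecg$mv
  n <- length(x)
  if (n == 0L) return(numeric(0))
  e <- x^2
  e_short <- moving_avg(e, round(short_s * ecg$fs))
  e_long <- moving_avg(e, round(long_s * ecg$fs))
  z <- moving_avg(e, max(1L, round(0.02 * ecg$fs)))
  y <- (e_short / (e_long + eps)) * z
  if (max(y) <= 0) return(numeric(0))
  md_a <- stats::mad(y)
  thr <- if (md_a > 0) stats::median(y) + thresh_mads * md_a else 0.3 * max(y)
  if (!any(y > thr)) return(numeric(0))
  ## local maxima above threshold
  cand <- which(y > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[y[cand] >= y[cand - 1L] & y[cand] >= y[cand + 1L]]
  if (length(cand) == 0L) return(numeric(0))
  ## strongest-first refractory suppression
  ord <- cand[order(y[cand], decreasing = TRUE)]
  ref_n <- round(refractory * ecg$fs)
  taken <- integer(0)
  for (i in ord) {
    if (length(taken) == 0L || all(abs(taken - i) >= ref_n)) {
      taken <- c(taken, i)
    }
  }
  ## refine to the local energy maximum
  hw <- max(1L, round(0.02 * ecg$fs))
  refined <- vapply(sort(taken), function(i) {
    lo <- max(1L, i - hw); hi <- min(n, i + hw)
    lo - 1L + which.max(z[lo:hi])
  }, 0)
  ## second pass: the adaptive threshold can sit far below the QRS peaks
  ## when the enhanced signal is near zero between beats, letting isolated
  ## noise crossings through; true peaks cluster orders of magnitude above
  ## them, so drop detections below 10% of the median detected height
  py <- y[refined]
  refined <- refined[py >= 0.1 * stats::median(py)]
  sort(ecg$time[refined])
}

#' Correct RR artifacts against the local median
#'
#' Flags interval `i` when it deviates from the median of its up-to-60
#' neighbouring intervals (30 per side, the candidate excluded, truncated at
#' the edges) by more than `k` local standard deviations, then replaces
#' flagged values by cubic-spline interpolation over beat index through the
#' retained intervals (nearest retained value at the edges).
#'
#' @param rr an [rr_series()].
#' @param k SD multiplier.
#' @param neighbors total neighbourhood size.
#' @return list with `rr` (corrected series, artifact flags set),
#'   `artifact_rate` and `flagged` (indices).
#' @export
correct_rr <- function(rr, k = 3, neighbors = 60) {
  x <- rr$rr
  n <- length(x)
  if (n == 0L) return(list(rr = rr, artifact_rate = 0, flagged = integer(0)))
  half <- neighbors %/% 2L
  flagged <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    nb <- x[lo:hi][-(i - lo + 1L)]
    if (length(nb) < 3L) next
    s <- sd0(nb)
    if (s == 0) {
      flagged[i] <- x[i] != stats::median(nb)
    } else {
      flagged[i] <- abs(x[i] - stats::median(nb)) > k * s
    }
  }
  rate <- mean(flagged)
  if (all(flagged)) {
    return(list(rr = rr, artifact_rate = 1, flagged = which(flagged),
                invalid = TRUE))
  }
  x2 <- x
  if (any(flagged)) {
    good <- which(!flagged)
    bad <- which(flagged)
    inner <- bad[bad > min(good) & bad < max(good)]
    outer <- setdiff(bad, inner)
    if (length(inner) > 0L) {
      x2[inner] <- stats::spline(good, x[good], xout = inner,
                                 method = "fmm")$y
    }
    if (length(outer) > 0L) {
      x2[outer] <- x[good[vapply(outer, function(b)
        which.min(abs(good - b)), 1L)]]
    }
  }
  beat_time <- rr$beat_time[1L] + c(0, cumsum(x2))
  list(rr = rr_series(beat_time, artifact = flagged),
       artifact_rate = rate, flagged = which(flagged))
}

#' Window validity under the 5% artifact rule
#'
#' @param artifact_rate fraction of beats flagged as artifacts, in [0, 1].
#' @return TRUE iff the rate is strictly below 0.05.
#' @export
validate_window <- function(artifact_rate) {
  stopifnot(artifact_rate >= 0, artifact_rate <= 1)
  artifact_rate < 0.05
}

#' Time-domain HRV metrics
#'
#' @param rr numeric RR intervals in seconds (>= 2 values).
#' @return list(BPM, SDNN, RMSSD); SDNN and RMSSD in milliseconds.
#' @export
time_domain <- function(rr) {
  if (length(rr) < 2L) stop_config("need at least 2 RR intervals")
  list(BPM = 60 / mean(rr),
       SDNN = stats::sd(rr) * 1000,
       RMSSD = sqrt(mean(diff(rr)^2)) * 1000)
}

## Hann-windowed Welch PSD, one-sided, density normalised so that
## sum(psd) * df = variance of the (detrended) input.
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg <- min(seg_len, n)
  step <- max(1L, floor(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  u <- sum(w^2)
  m <- seg %/% 2L
  acc <- numeric(m + 1L)
  for (s in starts) {
    xi <- x[s:(s + seg - 1L)]
    xi <- xi - mean(xi)
    sp <- abs(stats::fft(xi * w))^2 / (u * fs)
    half <- sp[1:(m + 1L)]
    if (seg %% 2L == 0L) {
      half[2:m] <- half[2:m] * 2
    } else {
      half[2:(m + 1L)] <- half[2:(m + 1L)] * 2
    }
    acc <- acc + half
  }
  psd <- acc / length(starts)
  freq <- (0:m) * fs / seg
  list(freq = freq, psd = psd)
}

#' Frequency-domain HRV metrics
#'
#' The RR tachogram is cubic-spline interpolated to a uniform 4 Hz grid,
#' linearly detrended, and its Welch power spectrum (60 s Hann segments,
#' 50% overlap) integrated over the LF band (0.04--0.15 Hz) and an
#' exercise-extended HF band (0.15--1.5 Hz, upper edge raised to cover
#' respiratory frequency during running). `pLF`/`pHF` normalise each band
#' by the analysed in-band variance so they sum to one.
#'
#' @param rr an [rr_series()] covering the analysis window.
#' @param fs_interp tachogram interpolation rate (Hz).
#' @param lf,hf numeric length-2 band edges (Hz).
#' @param seg_s Welch segment length (s).
#' @return list(LF, HF, pLF, pHF, LF_HF); LF/HF in ms^2, ratio dimensionless
#'   (NA when HF power is zero).
#' @export
frequency_domain <- function(rr, fs_interp = 4, lf = c(0.04, 0.15),
                             hf = c(0.15, 1.5), seg_s = 60) {
  bt <- rr$beat_time[-1L]  # interval i ends at beat i+1
  x <- rr$rr * 1000        # ms
  if (length(x) < 8L) stop_config("too few intervals for spectral analysis")
  tt <- seq(min(bt), max(bt), by = 1 / fs_interp)
  xi <- stats::spline(bt, x, xout = tt, method = "fmm")$y
  fit <- stats::lm.fit(cbind(1, tt), xi)
  xi <- fit$residuals
  ps <- welch_psd(xi, fs_interp, seg_len = round(seg_s * fs_interp))
  df <- ps$freq[2L] - ps$freq[1L]
  band_power <- function(b) sum(ps$psd[ps$freq >= b[1L] & ps$freq < b[2L]]) * df
  LF <- band_power(lf)
  HF <- band_power(hf)
  tot <- LF + HF
  list(LF = LF, HF = HF,
       pLF = if (tot > 0) LF / tot else NA_real_,
       pHF = if (tot > 0) HF / tot else NA_real_,
       LF_HF = if (HF > 0) LF / HF else NA_real_)
}

#' Poincare plot descriptors
#'
#' SD1 and SD2 are the dispersions across and along the identity line of the
#' lag-1 return map of successive RR intervals:
#' `SD1 = RMS((rr[i+1]-rr[i])/sqrt(2))` (the difference series is treated as
#' zero-mean, making `SD1 = RMSSD/sqrt(2)` an exact identity) and
#' `SD2 = SD((rr[i+1]+rr[i])/sqrt(2))` (sample SD about the mean).
#'
#' @param rr numeric RR intervals in seconds (>= 3 values).
#' @return list(SD1, SD2, SD1_SD2) in milliseconds (ratio dimensionless,
#'   NA when SD2 = 0).
#' @export
poincare <- function(rr) {
  if (length(rr) < 3L) stop_config("need at least 3 RR intervals")
  d <- diff(rr)
  s <- rr[-1L] + rr[-length(rr)]
  SD1 <- sqrt(mean((d / sqrt(2))^2)) * 1000
  SD2 <- stats::sd(s / sqrt(2)) * 1000
  list(SD1 = SD1, SD2 = SD2,
       SD1_SD2 = if (SD2 > 0) SD1 / SD2 else NA_real_)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' The mean-centred series is integrated; for each box size `n` the profile
#' is split into non-overlapping boxes (segmenting from both the start and
#' the end of the series, averaged), linearly detrended per box, and the
#' fluctuation `F(n)` computed as the root-mean-square residual, with the
#' finite-size correction `F(n) / sqrt(1 - 4/n^2)` that removes the
#' small-box bias of order-1 detrending (exact for uncorrelated data). The
#' exponent is the least-squares slope of `log F(n)` vs `log n`. The
#' short-term exponent uses integer box widths strictly inside (4, 16); the
#' long-term one strictly inside (16, 64).
#'
#' @param x numeric series (e.g. RR intervals).
#' @param scale_min,scale_max open interval bounds for the box widths.
#' @param n_scales number of log-spaced box sizes.
#' @return the scaling exponent, or NA when fewer than 3 usable scales.
#' @export
dfa <- function(x, scale_min = 4, scale_max = 16, n_scales = 10) {
  x <- x[is.finite(x)]
  N <- length(x)
  scales <- unique(round(exp(seq(log(scale_min + 1), log(scale_max - 1),
                                 length.out = n_scales))))
  scales <- scales[scales > scale_min & scales < scale_max & scales <= N %/% 2L]
  if (length(scales) < 3L || stats::sd(x) == 0) return(NA_real_)
  y <- cumsum(x - mean(x))
  fn <- vapply(scales, function(s) {
    n_box <- N %/% s
    ## residual-maker for an order-1 fit on 1..s, applied to all boxes at once
    X <- cbind(1, seq_len(s))
    M <- diag(s) - X %*% solve(crossprod(X), t(X))
    res2 <- 0
    for (rev_pass in c(FALSE, TRUE)) {
      yy <- if (rev_pass) rev(y) else y
      Y <- matrix(yy[seq_len(n_box * s)], nrow = s)
      res2 <- res2 + sum((M %*% Y)^2)
    }
    sqrt(res2 / (2 * n_box * s)) / sqrt(1 - 4 / s^2)
  }, 0)
  ok <- fn > 0
  if (sum(ok) < 3L) return(NA_real_)
  unname(stats::coef(stats::lm(log(fn[ok]) ~ log(scales[ok])))[2L])
}

#' Cardiac cost
#'
#' Heart rate divided by running speed.
#'
#' @param bpm heart rate in beats/min.
#' @param speed mean speed over the window (m/s); non-positive gives NA.
#' @return beats/min per m/s.
#' @export
cardiac_cost <- function(bpm, speed) {
  ifelse(is.finite(speed) & speed > 0, bpm / speed, NA_real_)
}

#' Per-window heart-rate dynamics features
#'
#' Runs the full HR feature chain on an RR series: 120 s windows every 10 s,
#' per-window artifact correction and 5% validity rule, then time-domain,
#' frequency-domain and non-linear metrics. Invalid windows propagate as
#' missing values (never zero).
#'
#' @param rr an [rr_series()] for the whole race (race time origin 0).
#' @param speed optional data.frame(time, speed) for cardiac cost.
#' @param win_length,win_overlap window geometry (s).
#' @return data.frame, one row per window, with window_center, validity,
#'   artifact_rate and the metric columns (BPM, SDNN, RMSSD, LF, HF, pLF,
#'   pHF, LF_HF, SD1, SD2, SD1_SD2, DFA_a1, DFA_a2, CC).
#' @export
hr_features <- function(rr, speed = NULL, win_length = 120,
                        win_overlap = 110) {
  duration <- max(rr$beat_time)
  wins <- window_stream(duration, win_length, win_overlap)
  out <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    sel <- rr$beat_time >= wins$start[w] & rr$beat_time < wins$end[w]
    row <- list(window_center = wins$center[w], valid = FALSE,
                artifact_rate = NA_real_,
                BPM = NA_real_, SDNN = NA_real_, RMSSD = NA_real_,
                LF = NA_real_, HF = NA_real_, pLF = NA_real_,
                pHF = NA_real_, LF_HF = NA_real_, SD1 = NA_real_,
                SD2 = NA_real_, SD1_SD2 = NA_real_, DFA_a1 = NA_real_,
                DFA_a2 = NA_real_, CC = NA_real_)
    bt <- rr$beat_time[sel]
    if (length(bt) >= 10L) {
      cor <- correct_rr(rr_series(bt))
      row$artifact_rate <- cor$artifact_rate
      row$valid <- validate_window(cor$artifact_rate)
      if (row$valid) {
        x <- cor$rr$rr
        td <- time_domain(x)
        row[names(td)] <- td
        fd <- try(frequency_domain(cor$rr), silent = TRUE)
        if (!inherits(fd, "try-error")) row[names(fd)] <- fd
        pc <- poincare(x)
        row[names(pc)] <- pc
        row$DFA_a1 <- dfa(x, 4, 16)
        row$DFA_a2 <- dfa(x, 16, 64)
        if (!is.null(speed)) {
          v <- mean(speed$speed[speed$time >= wins$start[w] &
                                  speed$time < wins$end[w]])
          row$CC <- cardiac_cost(row$BPM, v)
        }
      }
    }
    out[[w]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}
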