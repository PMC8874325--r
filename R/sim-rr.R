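## RR-interval and ECG synthesis with known ground truth.

#' Fractal (power-law) Gaussian noise
#'
#' Generates a zero-mean Gaussian series whose power spectrum follows
#' `f^-beta` with `beta = 2*alpha - 1`, so that detrended fluctuation
#' analysis of the series yields a scaling exponent close to `alpha`
#' (`alpha = 0.5` is white noise, `alpha = 1` is 1/f "pink" noise).
#' Synthesis is spectral: unit-variance complex Gaussian coefficients are
#' shaped by the target amplitude spectrum and inverted by FFT, then the
#' series is standardised to `sd`.
#'
#' @param n number of samples.
#' @param alpha target DFA scaling exponent (0.5 <= alpha <= 1.5 sensible).
#' @param sd standard deviation of the output.
#' @return numeric vector of length `n`.
#' @export
colored_noise <- function(n, alpha = 0.5, sd = 1) {
  if (n < 1L) return(numeric(0))
  if (sd == 0) return(rep(0, n))
  beta <- 2 * alpha - 1
  if (abs(beta) < 1e-12) {
    x <- stats::rnorm(n)
  } else {
    m <- n %/% 2L
    f <- seq_len(m) / n
    amp <- f ^ (-beta / 2)
    re <- stats::rnorm(m)
    im <- stats::rnorm(m)
    spec <- complex(real = re, imaginary = im) * amp
    full <- complex(real = rep(0, n))
    full[2L:(m + 1L)] <- spec
    if (n %% 2L == 0L) {
      full[m + 1L] <- complex(real = Re(spec[m]) * sqrt(2), imaginary = 0)
      if (m > 1L) full[n:(n - m + 2L)] <- Conj(spec[1L:(m - 1L)])
    } else {
      full[n:(n - m + 1L)] <- Conj(spec)
    }
    x <- Re(stats::fft(full, inverse = TRUE)) / n
  }
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) rep(0, n) else x * (sd / s)
}

#' RR interval series container
#'
#' @param beat_time strictly increasing beat times in seconds (n beats).
#' @param artifact logical flag per RR interval (length n-1), TRUE where the
#'   interval is known/suspected to be corrupted.
#' @return object of class `rr_series` with fields `beat_time` (n), `rr`
#'   (n-1, seconds, `rr[i] = beat_time[i+1] - beat_time[i]`) and `artifact`.
#' @export
rr_series <- function(beat_time, artifact = NULL) {
  beat_time <- as.numeric(beat_time)
  if (length(beat_time) >= 2L && any(diff(beat_time) <= 0)) {
    stop_config("beat_time must be strictly increasing")
  }
  rr <- diff(beat_time)
  if (is.null(artifact)) artifact <- rep(FALSE, length(rr))
  structure(list(beat_time = beat_time, rr = rr,
                 artifact = as.logical(artifact)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s, mean RR %.3f s, %d flagged\n",
              length(x$beat_time), diff(range(x$beat_time)),
              mean(x$rr), sum(x$artifact)))
  invisible(x)
}

## Instantaneous RR model shared by the generator and its documentation:
## RR(t) = baseline + drift * t/T + lf_amp sin(2 pi 0.1 t)
##                      + hf_amp sin(2 pi 0.3 t) + fractal noise
rr_model_value <- function(t, duration, cfg) {
  cfg$rr_baseline + cfg$rr_drift_slope * (t / duration) +
    cfg$lf_amp * sin(2 * pi * 0.1 * t) +
    cfg$hf_amp * sin(2 * pi * 0.3 * t)
}

#' Generate a subject's RR interval series
#'
#' Beat times are produced iteratively from an instantaneous RR model:
#' baseline plus linear drift over the race fraction, sinusoidal modulation
#' at 0.1 Hz (LF) and 0.3 Hz (HF, respiratory surrogate), and fractal
#' Gaussian noise calibrated to the configured DFA exponent. Intervals are
#' clipped below at 0.25 s.
#'
#' @param cfg a [sim_config()].
#' @param subject subject index in 1..n_subjects.
#' @return list with `rr` (an [rr_series()]) and `truth` (list with
#'   `beat_times` and the noise-free model parameters).
#' @export
generate_rr_series <- function(cfg, subject = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  duration <- cfg$race_duration[subject]
  if (duration <= 0) stop_config("race duration must be positive")
  n_max <- ceiling(duration / max(0.25, cfg$rr_baseline +
                                    min(0, cfg$rr_drift_slope))) + 16L
  beat_time <- with_seed(substream_seed(cfg$seed, subject, 11L), {
    noise <- colored_noise(n_max, cfg$hurst_alpha_target, cfg$rr_noise_sd)
    bt <- numeric(n_max)
    t <- 0
    k <- 0L
    while (t <= duration && k < n_max) {
      k <- k + 1L
      bt[k] <- t
      rr_k <- rr_model_value(t, duration, cfg) + noise[k]
      t <- t + max(0.25, rr_k)
    }
    bt[seq_len(k)]
  })
  list(rr = rr_series(beat_time),
       truth = list(beat_times = beat_time, duration = duration,
                    alpha_target = cfg$hurst_alpha_target))
}

#' Synthesize a single-lead ECG stream from beat times
#'
#' Places one stylised biphasic QRS template (a Ricker wavelet, ~50 ms
#' support, unit peak) at each beat time and adds white Gaussian noise at
#' the requested SNR, defined as usual on power: the noise SD is the clean
#' signal's RMS divided by `10^(snr_db/20)`. Morphology realism is a
#' non-goal: only R-peak timing matters downstream.
#'
#' @param rr an [rr_series()].
#' @param fs sampling rate in Hz.
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noise-free.
#' @param seed integer seed for the noise.
#' @return object of class `ecg_stream`: list(time, mv, fs).
#' @export
synthesize_ecg <- function(rr, fs = 250, snr_db = Inf, seed = 1L) {
  if (fs <= 0) stop_config("fs must be positive")
  if (length(rr$beat_time) == 0L) {
    return(structure(list(time = numeric(0), mv = numeric(0), fs = fs),
                     class = "ecg_stream"))
  }
  duration <- max(rr$beat_time) + 0.5
  n <- ceiling(duration * fs)
  time <- (seq_len(n) - 1L) / fs
  mv <- numeric(n)
  s <- 0.010  # template width parameter (s)
  half <- ceiling(4 * s * fs)
  tpl_t <- (-half:half) / fs
  tpl <- (1 - (tpl_t / s)^2) * exp(-tpl_t^2 / (2 * s^2))
  for (bt in rr$beat_time) {
    c0 <- round(bt * fs) + 1L
    idx <- (c0 - half):(c0 + half)
    keep <- idx >= 1L & idx <= n
    mv[idx[keep]] <- mv[idx[keep]] + tpl[keep]
  }
  if (is.finite(snr_db)) {
    sd_n <- sqrt(mean(mv^2)) / 10^(snr_db / 20)
    mv <- mv + with_seed(seed, stats::rnorm(n, sd = sd_n))
  }
  structure(list(time = time, mv = mv, fs = fs), class = "ecg_stream")
}

#' Inject RR artifacts emulating missed/extra beat detections
#'
#' A random subset of intervals is halved (spurious extra detection) or
#' doubled (missed beat), mimicking artifacts caused by electrode movement
#' and poor skin contact. Beat times are rebuilt from the perturbed
#' intervals.
#'
#' @param rr an [rr_series()].
#' @param rate fraction of intervals to perturb, in [0, 0.5).
#' @param seed integer seed.
#' @return list with `rr` (perturbed series) and `indices` (perturbed
#'   interval indices, increasing).
#' @export
inject_rr_artifacts <- function(rr, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.5) stop_config("rate must lie in [0, 0.5)")
  n <- length(rr$rr)
  if (rate == 0 || n == 0L) return(list(rr = rr, indices = integer(0)))
  k <- round(rate * n)
  if (k == 0L) return(list(rr = rr, indices = integer(0)))
  out <- with_seed(seed, {
    idx <- sort(sample.int(n, k))
    fac <- ifelse(stats::runif(k) < 0.5, 0.5, 2)
    list(idx = idx, fac = fac)
  })
  rr2 <- rr$rr
  rr2[out$idx] <- rr2[out$idx] * out$fac
  beat_time <- rr$beat_time[1L] + c(0, cumsum(rr2))
  list(rr = rr_series(beat_time), indices = out$idx)
}
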