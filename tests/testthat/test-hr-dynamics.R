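## Independent DFA oracle: naive per-box lm() loops, no shared code with
## dfa() beyond the definition itself.
dfa_oracle <- function(x, scale_min, scale_max, n_scales = 10) {
  N <- length(x)
  scales <- unique(round(exp(seq(log(scale_min + 1), log(scale_max - 1),
                                 length.out = n_scales))))
  scales <- scales[scales > scale_min & scales < scale_max & scales <= N %/% 2]
  y <- cumsum(x - mean(x))
  fn <- sapply(scales, function(s) {
    n_box <- N %/% s
    res2 <- 0
    for (pass in 1:2) {
      yy <- if (pass == 2) rev(y) else y
      for (b in seq_len(n_box)) {
        seg <- yy[((b - 1) * s + 1):(b * s)]
        fit <- stats::lm(seg ~ seq_len(s))
        res2 <- res2 + sum(stats::resid(fit)^2)
      }
    }
    sqrt(res2 / (2 * n_box * s)) / sqrt(1 - 4 / s^2)
  })
  unname(stats::coef(stats::lm(log(fn) ~ log(scales)))[2])
}

test_that("window_stream reproduces the 120 s / 10 s protocol geometry", {
  w <- window_stream(600)
  expect_equal(nrow(w), 49L)
  expect_equal(w$start[1], 0)
  expect_equal(w$end[49], 600)
  expect_equal(unique(diff(w$start)), 10)

  expect_equal(nrow(window_stream(120)), 1L)
  expect_warning(w0 <- window_stream(119), "shorter")
  expect_equal(nrow(w0), 0L)
  expect_error(window_stream(600, length = 120, overlap = 120), "overlap")
})

test_that("time-domain metrics match closed-form values", {
  td <- time_domain(rep(1, 120))
  expect_equal(td$BPM, 60)
  expect_equal(td$SDNN, 0)
  expect_equal(td$RMSSD, 0)

  rr <- rep(c(0.9, 1.1), 50)
  td2 <- time_domain(rr)
  expect_equal(td2$RMSSD, 200)
  expect_equal(td2$SDNN, 0.1 * sqrt(100 / 99) * 1000)
  expect_equal(td2$BPM, 60)

  expect_error(time_domain(1), "at least 2")
})

test_that("Poincare descriptors satisfy the RMSSD identity and an eigen oracle", {
  rr <- with_seed(10, 0.8 + cumsum(rnorm(500, 0, 0.005)) + rnorm(500, 0, 0.02))
  pc <- poincare(rr)
  td <- time_domain(rr)
  ## exact identity SD1 = RMSSD / sqrt(2)
  expect_lt(abs(pc$SD1 - td$RMSSD / sqrt(2)), 1e-9)

  ## SD2 oracle via the lag-1 covariance structure
  x <- rr[-length(rr)]; y <- rr[-1]
  sd2_oracle <- sqrt((stats::var(x) + stats::var(y) +
                        2 * stats::cov(x, y)) / 2) * 1000
  expect_lt(abs(pc$SD2 - sd2_oracle), 1e-9)

  ## constant series degenerates cleanly
  pc0 <- poincare(rep(0.8, 50))
  expect_equal(pc0$SD1, 0)
  expect_equal(pc0$SD2, 0)
  expect_true(is.na(pc0$SD1_SD2))

  expect_error(poincare(c(1, 1)), "at least 3")
})

test_that("DFA agrees with a brute-force oracle and degenerates to NA", {
  x <- with_seed(21, rnorm(400))
  expect_lt(abs(dfa(x, 4, 16) - dfa_oracle(x, 4, 16)), 1e-9)
  y <- with_seed(22, colored_noise(400, 1.0))
  expect_lt(abs(dfa(y, 16, 64) - dfa_oracle(y, 16, 64)), 1e-9)

  ## ordering property: pink scales faster than white (same seed budget)
  a_w <- mean(with_seed(23, replicate(20, dfa(colored_noise(800, 0.5), 4, 16))))
  a_p <- mean(with_seed(24, replicate(20, dfa(colored_noise(800, 1.0), 4, 16))))
  expect_gt(a_p, a_w + 0.2)

  ## degenerate inputs
  expect_true(is.na(dfa(rep(1, 100), 4, 16)))   # zero variance
  expect_true(is.na(dfa(rnorm(8), 4, 16)))      # too short for 3 scales
})

test_that("frequency-domain powers localize and normalize", {
  ## pure 0.3 Hz modulation: nearly all in-band power in HF
  t <- cumsum(rep(0.8, 400))
  rr_hf <- rr_series(c(0, t) + 0)
  rr_hf$rr <- 0.8 + 0.02 * sin(2 * pi * 0.3 * t)
  rr_hf$beat_time <- c(0, cumsum(rr_hf$rr))
  fd <- frequency_domain(rr_hf)
  expect_gt(fd$pHF, 0.95)

  ## pure 0.1 Hz modulation: LF
  rr_lf <- rr_hf
  rr_lf$rr <- 0.8 + 0.02 * sin(2 * pi * 0.1 * t)
  rr_lf$beat_time <- c(0, cumsum(rr_lf$rr))
  fd2 <- frequency_domain(rr_lf)
  expect_gt(fd2$pLF, 0.95)

  ## normalization identity on both
  expect_lt(abs(fd$pLF + fd$pHF - 1), 1e-9)
  expect_lt(abs(fd2$pLF + fd2$pHF - 1), 1e-9)
  ## and on a noisy series
  rr_n <- with_seed(30, {
    r <- 0.8 + rnorm(400, 0, 0.03)
    rr_series(c(0, cumsum(r)))
  })
  fd3 <- frequency_domain(rr_n)
  expect_lt(abs(fd3$pLF + fd3$pHF - 1), 1e-9)
  expect_gte(fd3$LF, 0)
  expect_gte(fd3$HF, 0)

  expect_error(frequency_domain(rr_series(c(0, 1, 2))), "too few")
})

test_that("QRS detection recovers clean and noisy beat times", {
  bt <- cumsum(c(0.5, rep(c(0.78, 0.84, 0.8), 20)))
  rr <- rr_series(bt)

  ## noise-free: every beat within 1 sample at 1000 Hz
  ecg <- resample_linear(synthesize_ecg(rr, fs = 250, snr_db = Inf), 1000)
  det <- detect_qrs(ecg)
  expect_equal(length(det), length(bt))
  expect_lt(max(abs(det - bt)), 0.002)

  ## 10 dB: sensitivity and precision at 10 ms tolerance
  ecg10 <- resample_linear(synthesize_ecg(rr, fs = 250, snr_db = 10,
                                          seed = 5), 1000)
  sc <- beat_match(detect_qrs(ecg10), bt)
  expect_gte(sc["sens"], 0.99)
  expect_gte(sc["prec"], 0.99)

  ## refractory period enforced
  expect_true(all(diff(det) >= 0.25))

  ## silent and empty streams yield no beats
  flat <- structure(list(time = seq(0, 10, by = 1e-3),
                         mv = rep(0, 10001), fs = 1000),
                    class = "ecg_stream")
  expect_length(detect_qrs(flat), 0L)
  empty <- structure(list(time = numeric(0), mv = numeric(0), fs = 1000),
                     class = "ecg_stream")
  expect_length(detect_qrs(empty), 0L)

  ## resampling validation
  expect_error(resample_linear(ecg, fs_out = 100), "fs_out")
})

test_that("RR correction flags injected artifacts and spares clean data", {
  rr <- with_seed(40, rr_series(cumsum(c(1, 0.8 + rnorm(600, 0, 0.01)))))

  ## clean series: low false-flag rate and values untouched where unflagged
  cl <- correct_rr(rr)
  expect_lt(cl$artifact_rate, 0.02)

  ## 2% halved/doubled intervals: recall >= 0.90
  inj <- inject_rr_artifacts(rr, 0.02, seed = 6)
  co <- correct_rr(inj$rr)
  recall <- mean(inj$indices %in% co$flagged)
  expect_gte(recall, 0.90)
  ## corrected values land near the true intervals
  expect_lt(max(abs(co$rr$rr[inj$indices] - rr$rr[inj$indices])), 0.1)
  ## unflagged values are exactly preserved
  keep <- setdiff(seq_along(inj$rr$rr), co$flagged)
  expect_equal(co$rr$rr[keep], inj$rr$rr[keep])

  ## a constant series with one spike: the spike is flagged, zero-SD guarded
  x <- rep(0.8, 100); x[50] <- 1.6
  sp <- correct_rr(rr_series(c(0, cumsum(x))))
  expect_true(50 %in% sp$flagged)
  expect_equal(sp$rr$rr[50], 0.8)

  ## empty series passes through
  e <- correct_rr(rr_series(numeric(0)))
  expect_equal(e$artifact_rate, 0)
})

test_that("validity rule and cardiac cost behave at their boundaries", {
  expect_true(validate_window(0))
  expect_true(validate_window(0.049))
  expect_false(validate_window(0.05))
  expect_false(validate_window(1))
  expect_error(validate_window(-0.1))

  expect_equal(cardiac_cost(180, 3), 60)
  expect_true(is.na(cardiac_cost(180, 0)))
  expect_true(is.na(cardiac_cost(180, NA)))
  expect_equal(cardiac_cost(c(120, 150), c(2, 3)), c(60, 50))
})

test_that("hr_features chains windows, validity and metrics", {
  cfg <- quick_cfg(race_duration = 400, artifact_rate = 0)
  g <- generate_rr_series(cfg, 1)
  sp <- data.frame(time = seq(0, 400, by = 1), speed = 3)
  f <- hr_features(g$rr, speed = sp)
  expect_equal(nrow(f), nrow(window_stream(max(g$rr$beat_time))))
  expect_true(all(f$valid))
  ## invariants on every valid row
  expect_true(all(abs(f$pLF + f$pHF - 1) < 1e-9))
  expect_true(all(f$SD1 >= 0 & f$SD2 >= 0))
  expect_true(all(is.finite(f$BPM)))
  ## cardiac cost = BPM / 3 with the constant speed channel
  expect_equal(f$CC, f$BPM / 3)

  ## heavy corruption propagates NA, never zero
  inj <- inject_rr_artifacts(g$rr, 0.15, seed = 9)
  f2 <- hr_features(inj$rr)
  expect_true(any(!f2$valid))
  expect_true(all(is.na(f2$BPM[!f2$valid])))
})
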