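make_shock_stream <- function(fs, shift = 0, duration = 8) {
  time <- seq(0, duration, by = 1 / fs)
  si <- shock_pulse(time, 3 + shift, fs)
  imu_stream(time, cbind(AP = 0 * time, SI = si, ML = 0 * time),
             cbind(sagittal = 0 * time, frontal = 0 * time,
                   transverse = 0 * time), fs)
}

test_that("estimate_lag recovers known clock offsets", {
  a <- make_shock_stream(200)

  ## identical streams: zero lag
  expect_equal(estimate_lag(a, a), 0)

  ## b's shock happens 0.5 s later on b's clock => b runs late by 0.5 s
  b <- make_shock_stream(200, shift = 0.5)
  expect_equal(estimate_lag(a, b), 0.5, tolerance = 1 / 200 + 1e-9)
  ## antisymmetry
  expect_equal(estimate_lag(b, a), -0.5, tolerance = 1 / 200 + 1e-9)

  ## mixed rates resolve at the higher rate
  c512 <- make_shock_stream(512, shift = 0.35)
  expect_equal(estimate_lag(a, c512), 0.35, tolerance = 1 / 200 + 1e-9)

  ## pure-noise streams have no usable peak
  noise <- with_seed(1, {
    time <- seq(0, 8, by = 1 / 100)
    imu_stream(time,
               cbind(AP = stats::rnorm(length(time)),
                     SI = stats::rnorm(length(time)),
                     ML = stats::rnorm(length(time))),
               cbind(sagittal = 0 * time, frontal = 0 * time,
                     transverse = 0 * time), 100)
  })
  noise2 <- with_seed(2, {
    time <- seq(0, 8, by = 1 / 100)
    imu_stream(time,
               cbind(AP = stats::rnorm(length(time)),
                     SI = stats::rnorm(length(time)),
                     ML = stats::rnorm(length(time))),
               cbind(sagittal = 0 * time, frontal = 0 * time,
                     transverse = 0 * time), 100)
  })
  expect_error(estimate_lag(noise, noise2), "ambiguous")

  ## non-overlapping clocks are rejected
  late <- make_shock_stream(200)
  late$time <- late$time + 100
  expect_error(estimate_lag(a, late), "overlap")
})

test_that("generator foot/chest streams synchronize to the configured lag", {
  cfg <- quick_cfg(race_duration = 120, sync_lag = 0.35)
  rec <- simulate_subject(cfg, 1, signals = c("gait", "imu"))
  crop <- function(st, t1) {
    keep <- st$time <= t1
    imu_stream(st$time[keep], st$acc[keep, , drop = FALSE],
               st$gyro[keep, , drop = FALSE], st$fs)
  }
  lag <- estimate_lag(crop(rec$chest, 10), crop(rec$foot, 10))
  expect_equal(lag, 0.35, tolerance = 1 / 200 + 1e-9)
})

test_that("haversine distance matches reference values and metric axioms", {
  ## one degree of longitude at the equator
  expect_equal(haversine_m(0, 0, 0, 1), 111194.9, tolerance = 0.1 / 111194.9)
  ## identity and symmetry
  expect_equal(haversine_m(46.5, 6.6, 46.5, 6.6), 0)
  p <- list(c(46.5, 6.6), c(46.6, 6.7), c(47.0, 6.0))
  d12 <- haversine_m(p[[1]][1], p[[1]][2], p[[2]][1], p[[2]][2])
  d21 <- haversine_m(p[[2]][1], p[[2]][2], p[[1]][1], p[[1]][2])
  expect_equal(d12, d21)
  ## triangle inequality
  d13 <- haversine_m(p[[1]][1], p[[1]][2], p[[3]][1], p[[3]][2])
  d23 <- haversine_m(p[[2]][1], p[[2]][2], p[[3]][1], p[[3]][2])
  expect_lte(d13, d12 + d23 + 1e-9)
  ## antipodal points: half the sphere circumference
  expect_equal(haversine_m(0, 0, 0, 180), pi * 6371000)
  ## out-of-range coordinates rejected
  expect_error(haversine_m(91, 0, 0, 0), "range")
})

test_that("slope detection flags steep sections and spares flat/threshold ones", {
  cfg <- quick_cfg(race_duration = 600, mean_speed = 3,
                   slope_sections = cbind(1000, 200, 8))
  tr <- generate_gnss_track(cfg, 1)
  mask <- detect_slopes(tr, grade_threshold = 5, window = 100)
  truth <- attr(tr, "slope_truth")
  expect_equal(nrow(mask), 1L)
  ## detected interval covers at least 90% of the true section in time
  cover <- min(mask$end[1], truth[1, "end_s"]) -
    max(mask$start[1], truth[1, "start_s"])
  expect_gte(cover / (truth[1, "end_s"] - truth[1, "start_s"]), 0.9)

  ## flat track: empty mask
  flat <- generate_gnss_track(quick_cfg(race_duration = 600, mean_speed = 3), 1)
  expect_equal(nrow(detect_slopes(flat)), 0L)

  ## grade exactly at the threshold is NOT flagged (strict inequality)
  at5 <- generate_gnss_track(
    quick_cfg(race_duration = 600, mean_speed = 3,
              slope_sections = cbind(1000, 200, 5)), 1)
  expect_equal(nrow(detect_slopes(at5, grade_threshold = 5)), 0L)

  ## short track warns and returns an empty mask
  short <- generate_gnss_track(quick_cfg(race_duration = 20, mean_speed = 3), 1)
  expect_warning(m <- detect_slopes(short), "shorter")
  expect_equal(nrow(m), 0L)
})

test_that("exclusion masks validate and filter half-open intervals", {
  m <- exclusion_mask(c(30, 10), c(40, 20), c("slope", "transient"))
  expect_equal(m$start, c(10, 30))  # sorted
  expect_error(exclusion_mask(c(0, 5), c(10, 15)), "disjoint")

  df <- data.frame(time = c(9.99, 10, 15, 19.99, 20, 25))
  out <- exclude_intervals(df, exclusion_mask(10, 20))
  expect_equal(out$time, c(9.99, 20, 25))  # [10, 20) dropped

  ## empty/NULL mask is the identity
  expect_identical(exclude_intervals(df, NULL), df)
  empty <- exclusion_mask(numeric(0), numeric(0), character(0))
  expect_identical(exclude_intervals(df, empty), df)

  ## idempotence
  once <- exclude_intervals(df, exclusion_mask(10, 20))
  expect_identical(exclude_intervals(once, exclusion_mask(10, 20)), once)
})

test_that("2-SD outlier replacement interpolates and preserves clean data", {
  x <- c(1, 1.1, 0.9, 1, 25, 1.05, 0.95, 1)
  y <- remove_outliers_2sd(x)
  expect_lt(y[5], 2)
  expect_equal(y[-5], x[-5])
  ## replacement is the linear interpolation of the neighbours
  expect_equal(y[5], (x[4] + x[6]) / 2)

  ## constant signal (SD = 0) untouched
  z <- rep(3, 10)
  expect_identical(remove_outliers_2sd(z), z)

  ## clean Gaussian-free signal with no 2-SD violator untouched
  w <- c(1, 2, 3, 2, 1)
  expect_identical(remove_outliers_2sd(w, k = 3), w)

  ## windowing: an outlier outside every window survives, one inside is fixed
  x2 <- c(1, 1, 50, rep(1, 20))
  x2[15] <- 99
  y2 <- remove_outliers_2sd(x2, t = seq_along(x2),
                            windows = cbind(4, length(x2) + 1))
  expect_equal(y2[3], 50)
  expect_lt(y2[15], 50)
})

test_that("activity segmentation honours annotations and the heuristic", {
  ann <- data.frame(label = c("warmup", "race"), start = c(0, 600),
                    end = c(600, 6600))
  expect_identical(segment_activities(ann), ann)
  expect_error(segment_activities(data.frame(label = "walk", start = 0,
                                             end = 10)),
               "race")

  ## heuristic: quiet - active - quiet picks out the active bout
  fs <- 50
  time <- seq(0, 60, by = 1 / fs)
  amp <- ifelse(time > 20 & time < 50, 3, 0.01)
  acc <- with_seed(4, cbind(AP = amp * stats::rnorm(length(time)),
                            SI = amp * stats::rnorm(length(time)),
                            ML = amp * stats::rnorm(length(time))))
  st <- imu_stream(time, acc, acc * 0, fs)
  seg <- segment_activities(imu = st)
  expect_equal(seg$label, "race")
  expect_lt(abs(seg$start - 20), 3)
  expect_lt(abs(seg$end - 50), 3)
})
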