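## Independent Friedman oracle in the algebraically different tie-robust
## form: chi2 = (k-1) * sum_j (R_j - n(k+1)/2)^2 / sum_ij (r_ij - (k+1)/2)^2.
friedman_oracle <- function(m) {
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / sum((r - (k + 1) / 2)^2)
}

test_that("Friedman chi-squared agrees with two independent routes", {
  m <- with_seed(50, matrix(rnorm(13 * 3), 13, 3) +
                   matrix(rep(c(0, 0.5, 1), each = 13), 13, 3))
  fr <- friedman_W(m)

  ## brute-force oracle (different algebraic form, tie-robust)
  expect_lt(abs(fr$statistic - friedman_oracle(m)), 1e-9)

  ## stats::friedman.test cross-check (statistic and p)
  ref <- stats::friedman.test(m)
  expect_lt(abs(fr$statistic - unname(ref$statistic)), 1e-9)
  expect_lt(abs(fr$p - ref$p.value), 1e-12)

  ## with ties
  mt <- m; mt[3, ] <- c(1, 1, 2); mt[7, ] <- c(2, 2, 2)
  frt <- friedman_W(mt)
  expect_lt(abs(frt$statistic - friedman_oracle(mt)), 1e-9)
  expect_lt(abs(frt$statistic - unname(stats::friedman.test(mt)$statistic)),
            1e-9)

  ## monotone invariance: ranks are unchanged by strictly increasing maps
  expect_equal(friedman_W(exp(m))$statistic, fr$statistic)

  ## perfect concordance: Kendall's W = 1 exactly
  mc <- matrix(rep(c(1, 2, 3, 4), each = 8), 8, 4) +
    matrix(rnorm(32, 0, 1e-3), 8, 4) * 0  # deterministic
  frc <- friedman_W(mc)
  expect_equal(frc$es_F, 1)
  expect_equal(frc$statistic, 8 * (4 - 1))

  ## guards
  expect_error(friedman_W(m[, 1:2]), "3 conditions")
  expect_error(friedman_W(m[1, , drop = FALSE]), "2 complete")
  ## rows with NA are listwise-deleted
  mna <- m; mna[2, 1] <- NA
  expect_equal(friedman_W(mna)$n, 12L)
})

test_that("Wilcoxon signed-rank approximation tracks the exact test", {
  ## all-positive, distinct differences, n = 13: exact two-sided p = 2/2^13
  x <- (1:13) * 1.1; y <- as.numeric(1:13)
  w <- wilcoxon_es(x, y)
  exact <- 2 / 2^13
  expect_lt(abs(w$p - exact), 1e-12)
  expect_equal(w$N, 13L)
  expect_gt(w$Z, 0)

  ## random paired data, n <= 15: matches stats::wilcox.test exact route
  for (i in 1:10) {
    d <- with_seed(60 + i, list(a = rnorm(12), b = rnorm(12, 0.4)))
    w2 <- wilcoxon_es(d$a, d$b)
    ref <- stats::wilcox.test(d$a, d$b, paired = TRUE, exact = TRUE)
    expect_lt(abs(w2$p - ref$p.value), 1e-12)
  }

  ## zero differences dropped; all-zero collapses to the null
  expect_equal(wilcoxon_es(1:5, 1:5), list(Z = 0, p = 1, es_W = 0, N = 0L))
  w3 <- wilcoxon_es(c(1, 2, 3, 4), c(1, 2.5, 2.5, 3.5))
  expect_equal(w3$N, 3L)

  ## effect size bounded and non-negative
  expect_gte(w$es_W, 0)
  expect_lt(w$es_W, 1.1)

  ## symmetry: swapping the arguments flips Z
  expect_equal(wilcoxon_es(y, x)$Z, -w$Z)
})

test_that("significance stars follow the reported convention", {
  expect_equal(p_stars(c(0.04, 0.05, 0.01, 0.002, 0.0009, 0.0005)),
               c("*", "*", "**", "**", "***", "***"))
  expect_equal(p_stars(0.051), "")
})

test_that("design matrices pull the right conditions per subject", {
  mk_sfm <- function(vals, rof = 3:10) {
    lvl <- rep(NA_character_, 8)
    lvl[1] <- "L"; lvl[4] <- "M"; lvl[8] <- "H"
    data.frame(segment = 1:8, parameter = "t_c", kind = "biomech",
               median = vals, iqr = 0.01, normalized = vals / vals[1],
               n_samples = 50, rof = rof, delta_rof = rof - rof[1],
               delta_state = pool_delta_rof(rof - rof[1]),
               level = lvl)
  }
  sfm1 <- mk_sfm(seq(0.26, 0.273, length.out = 8))
  sfm2 <- mk_sfm(seq(0.25, 0.26, length.out = 8))
  dm <- design_matrix(list(sfm1, sfm2), "t_c", "segments")
  expect_equal(dim(dm), c(2L, 3L))
  expect_equal(unname(dm[1, "S1"]), 1)
  expect_equal(unname(dm[1, "S8"]), sfm1$normalized[8])

  dml <- design_matrix(list(sfm1, sfm2), "t_c", "rof_levels")
  expect_equal(unname(dml[1, "L"]), sfm1$normalized[1])
  expect_equal(unname(dml[1, "H"]), sfm1$normalized[8])
  expect_equal(unname(dml[1, "M"]), sfm1$normalized[4])

  dmd <- design_matrix(list(sfm1, sfm2), "t_c", "drof_states")
  ## state "0" only in segment 1; ">=5" pools segments with drof >= 5
  expect_equal(unname(dmd[1, "0"]), sfm1$normalized[1])
  expect_equal(unname(dmd[1, ">=5"]),
               stats::median(sfm1$normalized[sfm1$delta_rof >= 5]))
})

test_that("the battery reports Friedman plus the printed contrasts", {
  mk_sfm <- function(s) {
    set.seed(70 + s)
    vals <- 0.26 * (1 + 0.05 * (1:8) / 8) + rnorm(8, 0, 1e-4)
    rof <- c(3, 4, 4, 5, 6, 7, 8, 9)
    data.frame(segment = 1:8, parameter = "t_c", kind = "biomech",
               median = vals, iqr = 0.01, normalized = vals / vals[1],
               n_samples = 50, rof = rof, delta_rof = rof - rof[1],
               delta_state = pool_delta_rof(rof - rof[1]),
               level = ifelse(rof == 3, "L", ifelse(rof == 9, "H",
                              ifelse(rof == 6, "M", NA))))
  }
  sfms <- lapply(1:8, mk_sfm)
  bat <- run_battery(sfms, designs = c("segments", "drof_states"))
  expect_setequal(unique(bat$design), c("segments", "drof_states"))
  ## 1 friedman + 3 wilcoxon per design
  expect_equal(nrow(bat), 2L * 4L)
  expect_equal(sum(bat$test == "friedman"), 2L)
  expect_equal(unique(bat$contrast[bat$test == "friedman"]), "all")
  ## a monotone increase across all subjects is detected
  fr <- bat[bat$test == "friedman" & bat$design == "segments", ]
  expect_lt(fr$p, 0.01)
  expect_gt(fr$effect_size, 0.9)
  ## stars consistent with p everywhere
  expect_equal(bat$stars, ifelse(bat$p <= 0.05, p_stars(bat$p), ""))
})

test_that("the mixed model recovers known fixed effects", {
  sim <- with_seed(80, {
    subj <- rep(1:10, each = 7)
    drof <- rep(0:6, times = 10)
    perf <- ifelse(subj <= 5, "fast", "slow")
    b0 <- rnorm(10, 0, 0.02)[subj]
    b1 <- rnorm(10, 0, 0.004)[subj]
    resp <- 1 + 0.05 * drof + 0.03 * drof * (perf == "slow") +
      b0 + b1 * drof + rnorm(length(subj), 0, 0.01)
    data.frame(responder = resp, drof = drof, performance = perf,
               subject = subj)
  })
  fit <- fit_lme(sim)
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est["(Intercept)"]), 1, tolerance = 0.05)
  expect_equal(unname(est["drof"]), 0.05, tolerance = 0.3)
  expect_equal(unname(est["drof:performanceslow"]), 0.03, tolerance = 0.3)
  ## the fatigue slope is significant; CI and p agree on the call
  drow <- fit$fixed[fit$fixed$term == "drof", ]
  expect_true(drow$significant)
  expect_true(drow$ci_lo > 0)
  ## R2: conditional >= marginal, both in [0, 1]
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  expect_gte(fit$r2_marginal, 0)
  expect_lte(fit$r2_conditional, 1)

  ## pure fixed-effect data collapses the random slope -> singular flag
  sim0 <- sim
  sim0$responder <- 1 + 0.05 * sim0$drof +
    with_seed(81, rnorm(nrow(sim0), 0, 0.01))
  fit0 <- fit_lme(sim0)
  expect_true(is.logical(fit0$singular))
  expect_true(all(is.finite(fit0$fixed$estimate)))

  ## guards: single group rejected
  one <- sim[sim$performance == "fast", ]
  expect_error(fit_lme(one), "two performance groups")
})

test_that("lme_long stacks fast/slow subjects and drops the rest", {
  sfm <- data.frame(segment = 1:8, parameter = "BPM", kind = "physio",
                    median = 140 + 1:8, iqr = 1,
                    normalized = (140 + 1:8) / 141, n_samples = 40,
                    rof = 3:10, delta_rof = 0:7,
                    delta_state = pool_delta_rof(0:7),
                    level = NA)
  long <- lme_long(list(sfm, sfm, sfm), c("fast", "mid", "slow"), "BPM")
  expect_equal(nrow(long), 16L)
  expect_setequal(unique(long$performance), c("fast", "slow"))
  expect_setequal(unique(long$subject), c(1L, 3L))
  expect_equal(long$drof[1:8], 0:7)
})
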