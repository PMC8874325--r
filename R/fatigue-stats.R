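## Non-parametric battery and mixed-effects modelling.

#' Friedman test with Kendall's W effect size
#'
#' Within-subject mid-ranks with tie correction; the statistic is referred
#' to a chi-squared distribution with k-1 degrees of freedom and the effect
#' size is Kendall's coefficient of concordance
#' `W = chi^2 / (n (k - 1))`.
#'
#' @param m numeric matrix, subjects in rows, conditions in columns; rows
#'   with missing values are listwise-deleted.
#' @return list(statistic, p, es_F, n, k).
#' @export
friedman_W <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 3L) stop_config("need at least 3 conditions")
  if (n < 2L) stop_config("need at least 2 complete subjects")
  r <- t(apply(m, 1L, rank))
  Rj <- colSums(r)
  ## tie correction per row: sum over rows of sum(t^3 - t)
  tie <- sum(apply(r, 1L, function(u) {
    tab <- table(u)
    sum(tab^3 - tab)
  }))
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - tie / (k - 1)
  if (den <= 0) {
    chi2 <- 0
  } else {
    chi2 <- num / den
  }
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  list(statistic = chi2, p = p, es_F = chi2 / (n * (k - 1)), n = n, k = k)
}

#' Wilcoxon signed-rank test with |Z|/sqrt(N) effect size
#'
#' Paired two-sided signed-rank test: zero differences are dropped
#' (Wilcoxon's rule) and ranks are mid-ranks. The p-value uses the exact
#' signed-rank distribution for tie-free samples up to N = 50 and the
#' normal approximation with tie and continuity corrections otherwise. The
#' Z score always comes from the corrected normal approximation, and the
#' effect size is `|Z| / sqrt(N)` with N the number of non-zero-difference
#' pairs. No multiplicity correction is applied.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @return list(Z, p, es_W, N).
#' @export
wilcoxon_es <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  N <- length(d)
  if (N == 0L) return(list(Z = 0, p = 1, es_W = 0, N = 0L))
  r <- rank(abs(d))
  Wp <- sum(r[d > 0])
  mu <- N * (N + 1) / 4
  tab <- table(r)
  sig2 <- N * (N + 1) * (2 * N + 1) / 24 - sum(tab^3 - tab) / 48
  if (sig2 <= 0) return(list(Z = 0, p = 1, es_W = 0, N = N))
  cc <- sign(Wp - mu) * 0.5
  Z <- (Wp - mu - cc) / sqrt(sig2)
  ties <- any(duplicated(r))
  if (!ties && N <= 50L) {
    p <- if (Wp > mu) {
      2 * stats::psignrank(Wp - 1, N, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(Wp, N)
    }
    p <- min(1, p)
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
  }
  list(Z = Z, p = p, es_W = abs(Z) / sqrt(N), N = N)
}

## Significance stars per the reported convention.
p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "")))
}

## Per-subject condition values for the three designs; `sfm_list` is a list
## of per-subject segment feature matrices. Returns a subjects x conditions
## matrix for one parameter.
design_matrix <- function(sfm_list, parameter,
                          design = c("segments", "rof_levels", "drof_states"),
                          value_col = "normalized") {
  design <- match.arg(design)
  rows <- lapply(sfm_list, function(sfm) {
    d <- sfm[sfm$parameter == parameter, , drop = FALSE]
    if (design == "segments") {
      v <- d[[value_col]][match(c(1L, 5L, 8L), d$segment)]
      names(v) <- c("S1", "S5", "S8")
    } else if (design == "rof_levels") {
      v <- vapply(c("L", "M", "H"), function(l) {
        sel <- !is.na(d$level) & (d$level == l | d$level == "L=M=H")
        if (any(sel)) stats::median(d[[value_col]][sel], na.rm = TRUE)
        else NA_real_
      }, 0)
    } else {
      v <- vapply(c("0", "[1,2]", "[3,4]", ">=5"), function(st) {
        sel <- !is.na(d$delta_state) & d$delta_state == st
        if (any(sel)) stats::median(d[[value_col]][sel], na.rm = TRUE)
        else NA_real_
      }, 0)
    }
    v
  })
  do.call(rbind, rows)
}

#' Run the non-parametric statistical battery
#'
#' For every parameter and each requested design -- race segments (S1, S5,
#' S8), pooled ROF levels (L, M, H), and delta-ROF onset states (0 vs
#' [1,2], [3,4], >= 5) -- runs a Friedman test over the conditions plus the
#' printed pairwise Wilcoxon signed-rank contrasts, reporting effect sizes
#' and significance stars (p <= 0.05; `*` for (0.01, 0.05], `**` for
#' (0.001, 0.01], `***` below 0.001).
#'
#' @param sfm_list list of per-subject [segment_feature_matrix()] results.
#' @param parameters character vector of parameters to test (default: all
#'   present in the first subject).
#' @param designs subset of c("segments", "rof_levels", "drof_states").
#' @param value_col which column to test ("normalized" or "median").
#' @return data.frame with one row per parameter x design x contrast,
#'   columns: parameter, design, contrast, test, statistic, p, effect_size,
#'   n, k, stars.
#' @export
run_battery <- function(sfm_list, parameters = NULL,
                        designs = c("segments", "rof_levels", "drof_states"),
                        value_col = "normalized") {
  if (is.null(parameters)) parameters <- unique(sfm_list[[1L]]$parameter)
  contrasts <- list(
    segments = list(c("S1", "S5"), c("S5", "S8"), c("S1", "S8")),
    rof_levels = list(c("L", "M"), c("M", "H"), c("L", "H")),
    drof_states = list(c("0", "[1,2]"), c("0", "[3,4]"), c("0", ">=5"))
  )
  out <- list()
  for (p in parameters) {
    for (dg in designs) {
      m <- design_matrix(sfm_list, p, dg, value_col)
      fr <- try(friedman_W(m), silent = TRUE)
      if (!inherits(fr, "try-error")) {
        out[[length(out) + 1L]] <- data.frame(
          parameter = p, design = dg, contrast = "all",
          test = "friedman", statistic = fr$statistic, p = fr$p,
          effect_size = fr$es_F, n = fr$n, k = fr$k,
          stars = if (fr$p <= 0.05) p_stars(fr$p) else "")
      }
      for (ct in contrasts[[dg]]) {
        wc <- wilcoxon_es(m[, ct[1L]], m[, ct[2L]])
        out[[length(out) + 1L]] <- data.frame(
          parameter = p, design = dg,
          contrast = paste(ct, collapse = "|"),
          test = "wilcoxon", statistic = wc$Z, p = wc$p,
          effect_size = wc$es_W, n = wc$N, k = 2L,
          stars = if (wc$p <= 0.05) p_stars(wc$p) else "")
      }
    }
  }
  do.call(rbind, out)
}

#' Fit the performance-group linear mixed-effects model
#'
#' `responder ~ drof * performance + (drof | subject)` by maximum
#' likelihood: fixed effects for the fatigue score, the performance group
#' (fast vs slow) and their interaction, with per-subject random intercept
#' and slope. delta-ROF enters numerically (not pooled). Wald-style 95%
#' confidence intervals and p-values use a t reference distribution with
#' subject-level degrees of freedom (number of subjects minus the two
#' subject-level fixed terms), the standard small-sample correction for
#' mixed models where normal-quantile intervals undercover; an effect is
#' significant when p <= 0.05 and its CI excludes 0. The conditional R^2
#' follows the variance-partition formula: fixed variance is the variance
#' of the fixed-effect predictor, random variance is the mean of
#' `z_i' Sigma z_i` over observations, and both are referred to the total
#' including the residual variance. A singular random-slope fit is refitted
#' with a random intercept only and flagged.
#'
#' @param data data.frame with columns `responder`, `drof`, `performance`
#'   (factor/character, two groups) and `subject`.
#' @return list with `fixed` (data.frame: term, estimate, se, z, p, ci_lo,
#'   ci_hi, significant), `r2_conditional`, `r2_marginal`, `singular`
#'   (logical) and the fitted `model`.
#' @export
fit_lme <- function(data) {
  stopifnot(all(c("responder", "drof", "performance", "subject") %in%
                  names(data)))
  data <- data[stats::complete.cases(
    data[, c("responder", "drof", "performance", "subject")]), ]
  data$performance <- factor(data$performance)
  if (length(unique(data$performance)) < 2L) {
    stop_config("need two performance groups")
  }
  if (min(table(unique(data[, c("subject", "performance")])$performance)) < 2L) {
    stop_config("need >= 2 subjects per group")
  }
  ctl <- lme4::lmerControl(check.conv.singular = "ignore",
                           calc.derivs = FALSE)
  fit <- suppressWarnings(
    lme4::lmer(responder ~ drof * performance + (drof | subject),
               data = data, REML = FALSE, control = ctl))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    fit <- suppressWarnings(
      lme4::lmer(responder ~ drof * performance + (1 | subject),
                 data = data, REML = FALSE, control = ctl))
  }
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  z <- est / se
  df <- max(2L, length(unique(data$subject)) - 2L)
  p <- 2 * stats::pt(-abs(z), df)
  ci_lo <- est - stats::qt(0.975, df) * se
  ci_hi <- est + stats::qt(0.975, df) * se
  fixed <- data.frame(term = rownames(co), estimate = est, se = se, z = z,
                      p = p, ci_lo = ci_lo, ci_hi = ci_hi,
                      significant = p <= 0.05 & (ci_lo > 0 | ci_hi < 0),
                      row.names = NULL)
  ## variance partition
  X <- stats::model.matrix(fit)
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)$subject
  if (nrow(vc) == 2L) {
    d <- data$drof
    var_r <- mean(vc[1L, 1L] + 2 * vc[1L, 2L] * d + vc[2L, 2L] * d^2)
  } else {
    var_r <- vc[1L, 1L]
  }
  var_e <- stats::sigma(fit)^2
  tot <- var_f + var_r + var_e
  list(fixed = fixed,
       r2_conditional = if (tot > 0) (var_f + var_r) / tot else NA_real_,
       r2_marginal = if (tot > 0) var_f / tot else NA_real_,
       singular = singular, model = fit)
}

#' Long-format responder table for the mixed model
#'
#' Stacks per-subject segment feature matrices into the (responder, drof,
#' performance, subject) layout consumed by [fit_lme()], keeping only
#' subjects in the fast/slow groups.
#'
#' @param sfm_list list of per-subject [segment_feature_matrix()] results.
#' @param groups character vector of group labels per subject ("fast",
#'   "slow", or other labels which are dropped).
#' @param parameter which parameter becomes the responder.
#' @param value_col value column used as responder.
#' @return data.frame(responder, drof, performance, subject).
#' @export
lme_long <- function(sfm_list, groups, parameter, value_col = "normalized") {
  out <- list()
  for (s in seq_along(sfm_list)) {
    if (!groups[s] %in% c("fast", "slow")) next
    d <- sfm_list[[s]]
    d <- d[d$parameter == parameter, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      responder = d[[value_col]], drof = d$delta_rof,
      performance = groups[s], subject = s)
  }
  do.call(rbind, out)
}
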