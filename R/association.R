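## Linear and non-linear association between gait and heart-rate series.

#' Replace outliers inside non-overlapping 10-sample windows
#'
#' Within each consecutive block of `width` samples, values deviating from
#' the block median by more than `k` block standard deviations are replaced
#' by the block median (`blanket = TRUE` replaces every sample by the
#' median instead).
#'
#' @param x numeric series.
#' @param width block width in samples.
#' @param k SD multiplier.
#' @param blanket replace the whole block by its median.
#' @return cleaned numeric vector.
#' @export
median_window_clean <- function(x, width = 10, k = 2, blanket = FALSE) {
  n <- length(x)
  if (n == 0L) return(x)
  block <- (seq_len(n) - 1L) %/% width
  for (b in unique(block)) {
    idx <- which(block == b)
    med <- stats::median(x[idx])
    if (blanket) {
      x[idx] <- med
    } else {
      s <- sd0(x[idx])
      if (s > 0) {
        bad <- abs(x[idx] - med) > k * s
        x[idx][bad] <- med
      }
    }
  }
  x
}

#' Align a gait series with a heart-rate series inside one segment
#'
#' Both series are outlier-cleaned in non-overlapping 10-sample median
#' windows; the (denser) gait series is then averaged over 120 s windows
#' stepping 10 s -- the same geometry as the heart-rate features -- and both
#' are cropped to common window centers.
#'
#' @param biomech data.frame(time, value) of the gait parameter (per-cycle
#'   or denser).
#' @param physio data.frame(time, value) of the heart-rate metric at the
#'   10 s cadence (times = window centers).
#' @param seg_start,seg_end segment bounds (s).
#' @param win_length,win_step averaging geometry (s).
#' @param min_points minimum common points; below it NULL is returned.
#' @return list(x = biomech series, y = physio series, time) or NULL.
#' @export
align_series <- function(biomech, physio, seg_start, seg_end,
                         win_length = 120, win_step = 10, min_points = 5) {
  bi <- biomech[biomech$time >= seg_start & biomech$time < seg_end, ]
  ph <- physio[physio$time >= seg_start & physio$time < seg_end, ]
  ph <- ph[is.finite(ph$value), ]
  if (nrow(bi) < min_points || nrow(ph) < min_points) return(NULL)
  bi$value <- median_window_clean(bi$value)
  ph$value <- median_window_clean(ph$value)
  ## average the gait series on the heart-rate window grid
  centers <- ph$time
  x <- vapply(centers, function(ct) {
    sel <- bi$time >= ct - win_length / 2 & bi$time < ct + win_length / 2
    if (any(sel)) mean(bi$value[sel]) else NA_real_
  }, 0)
  ok <- is.finite(x)
  if (sum(ok) < min_points) return(NULL)
  list(x = x[ok], y = ph$value[ok], time = centers[ok])
}

#' Pearson correlation with a t-distribution p-value
#'
#' @param x,y equal-length numeric vectors; constant input yields NA.
#' @return list(r, p, n).
#' @export
pearson_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || sd0(x) == 0 || sd0(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Sample distance correlation (classical V-statistic)
#'
#' Pairwise Euclidean distance matrices of `x` and `y` are double-centered;
#' the squared distance covariance is the mean of their elementwise product
#' and the correlation normalises by the distance variances:
#' `dCor = dCov / sqrt(dVar_x dVar_y)`, 0 when either variance vanishes.
#' The estimator is the original biased one.
#'
#' @param x,y equal-length numeric vectors (length >= 5 recommended).
#' @return dCor in [0, 1].
#' @export
distance_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  dc <- function(v) {
    d <- as.matrix(stats::dist(v))
    d - rowMeans(d) - rep(colMeans(d), each = nrow(d)) + mean(d)
  }
  A <- dc(x); B <- dc(y)
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(0, dcov2) / sqrt(dvx * dvy))
}

#' Per subject-segment-pair association records
#'
#' For each subject, segment and (gait, heart-rate) parameter pair, aligns
#' the two series and computes Pearson r with its p-value and the distance
#' correlation. Default pairs: {t_c, FSA, k_vert, v, a_AP} x {BPM, SDNN,
#' DFA_a1, SD2}.
#'
#' @param biomech_streams per-subject named list of data.frame(time, value)
#'   gait series (list over subjects of lists over parameters).
#' @param physio_streams same structure for heart-rate series at 10 s
#'   cadence.
#' @param segments_list per-subject [split_race()] results.
#' @param biomech_names,physio_names parameter name sets forming the pairs.
#' @return data.frame(subject, segment, biomech, physio, pair, r, p, dcor,
#'   n); skipped (too short) alignments keep the row with NA measures.
#' @export
association_records <- function(biomech_streams, physio_streams,
                                segments_list,
                                biomech_names = c("t_c", "FSA", "k_vert",
                                                  "v", "a_AP"),
                                physio_names = c("BPM", "SDNN", "DFA_a1",
                                                 "SD2")) {
  out <- list()
  for (s in seq_along(biomech_streams)) {
    segs <- segments_list[[s]]
    for (bn in biomech_names) {
      for (pn in physio_names) {
        for (g in seq_len(nrow(segs))) {
          al <- align_series(biomech_streams[[s]][[bn]],
                             physio_streams[[s]][[pn]],
                             segs$start[g], segs$end[g])
          rec <- data.frame(subject = s, segment = segs$segment[g],
                            biomech = bn, physio = pn,
                            pair = paste(bn, pn, sep = "|"),
                            r = NA_real_, p = NA_real_, dcor = NA_real_,
                            n = 0L)
          if (!is.null(al)) {
            pe <- pearson_p(al$x, al$y)
            rec$r <- pe$r; rec$p <- pe$p; rec$n <- pe$n
            rec$dcor <- distance_correlation(al$x, al$y)
          }
          out[[length(out) + 1L]] <- rec
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Summarise association records per parameter pair
#'
#' Counts segment instances with a significant linear correlation
#' (p < 0.05), and reports the median (IQR) of r over the significant
#' records only and of dCor over all records.
#'
#' @param records an [association_records()] result.
#' @return data.frame(pair, n_attempted, n_significant, r_median, r_iqr,
#'   dcor_median, dcor_iqr).
#' @export
summarize_associations <- function(records) {
  out <- lapply(split(records, records$pair), function(d) {
    sig <- d[!is.na(d$p) & d$p < 0.05, , drop = FALSE]
    data.frame(pair = d$pair[1L],
               n_attempted = nrow(d),
               n_significant = nrow(sig),
               r_median = if (nrow(sig)) stats::median(sig$r) else NA_real_,
               r_iqr = if (nrow(sig)) iqr_lin(sig$r) else NA_real_,
               dcor_median = stats::median(d$dcor, na.rm = TRUE),
               dcor_iqr = iqr_lin(d$dcor))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
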