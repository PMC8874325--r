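#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so simulation substreams do not perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Derive a per-subject, per-signal RNG substream from a master seed.
## Offsets are fixed so the same (seed, subject, signal) always maps to the
## same substream; result kept inside the 32-bit integer range.
substream_seed <- function(seed, subject, offset) {
  (as.numeric(seed) * 101 + subject * 7919 + offset) %% 2147483629
}

## Linear-interpolation quantile (type 7) IQR.
iqr_lin <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 1L) return(NA_real_)
  unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))
}

## Sample standard deviation that tolerates length-1 input.
sd0 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

## Moving average by convolution, same length, edge-padded.
moving_avg <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  xp <- c(rep(x[1L], n), x, rep(x[length(x)], n))
  f <- stats::filter(xp, rep(1 / n, n), sides = 2)
  as.numeric(f[(n + 1L):(n + length(x))])
}

## Half-open interval membership: start <= t < end for any row of `ints`
## (matrix or data.frame with columns start, end).
in_intervals <- function(t, ints) {
  if (is.null(ints) || NROW(ints) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(NROW(ints))) {
    hit <- hit | (t >= ints[i, 1L] & t < ints[i, 2L])
  }
  hit
}

## Merge overlapping/adjacent half-open intervals given as a 2-column matrix.
merge_intervals <- function(m) {
  if (NROW(m) == 0L) return(matrix(numeric(0), ncol = 2L))
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (NROW(m) > 1L) {
    for (i in 2L:NROW(m)) {
      j <- NROW(out)
      if (m[i, 1L] <= out[j, 2L]) {
        out[j, 2L] <- max(out[j, 2L], m[i, 2L])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  unname(out)
}
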