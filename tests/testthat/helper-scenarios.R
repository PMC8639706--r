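# Shared scenario builders and independent oracles for the test suite.

# noise-free config: all observation noise off, no detection limit
quiet_config <- function(...) {
  sim_config(..., sensor_sd = 0, atpct_sd = 0, sensor_detection_limit = 0)
}

# total N and total 15N atoms at every step of a bottle series
series_totals <- function(series) {
  list(
    N = series$NH4 + series$NO2 + series$NO3,
    N15 = series$f15_NH4 * series$NH4 + series$f15_NO2 * series$NO2 +
      series$f15_NO3 * series$NO3)
}

# Brute-force MIC oracle: same grid family as mic() (equal-frequency bins on
# one axis, all contiguous interval partitions of the other axis) but the
# partition search enumerates every cut combination explicitly with combn()
# instead of dynamic programming.
mic_oracle <- function(x, y, alpha = 0.6) {
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) return(0)
  B <- max(4, n^alpha)
  xlog2x <- function(v) ifelse(v > 0, v * log2(v), 0)
  best <- 0
  for (swap in c(FALSE, TRUE)) {
    X <- if (swap) y else x
    Y <- if (swap) x else y
    for (b in 2:max(2L, floor(B / 2))) {
      amax <- floor(B / b)
      if (amax < 2) next
      yb <- nitroxr:::equifreq_bin(Y, b)
      ord <- order(X)
      xo <- X[ord]; ybo <- yb[ord]
      clump <- cumsum(c(TRUE, diff(xo) > 0))
      m <- clump[n]
      counts <- matrix(0L, m, b)
      for (i in seq_len(n)) counts[clump[i], ybo[i]] <- counts[clump[i], ybo[i]] + 1L
      ytot <- colSums(counts)
      Hy <- log2(n) - sum(xlog2x(ytot)) / n
      phi_interval <- function(lo, hi) {
        v <- colSums(counts[lo:hi, , drop = FALSE])
        xlog2x(sum(v)) - sum(xlog2x(v))
      }
      for (k in 2:min(amax, m)) {
        cuts <- utils::combn(m - 1, k - 1)
        for (j in seq_len(ncol(cuts))) {
          bounds <- c(0, cuts[, j], m)
          tot <- 0
          for (i in seq_len(k)) {
            tot <- tot + phi_interval(bounds[i] + 1, bounds[i + 1])
          }
          val <- (Hy - tot / n) / log2(min(k, b))
          if (val > best) best <- val
        }
      }
    }
  }
  min(best, 1)
}
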