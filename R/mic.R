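#' Maximal information coefficient (MIC)
#'
#' Dependence statistic in \[0, 1\] used together with r^2 to screen
#' dissolved-oxygen drawdown curves for nonlinearity: MIC is near 1 for any
#' noiseless functional relationship (linear or not), so a high MIC combined
#' with a low regression r^2 flags a nonlinear curve.
#'
#' For a grid of a x b cells the normalized mutual information is
#' I(a, b) / log2(min(a, b)); MIC is its maximum over all grids with
#' a, b >= 2 and a * b <= B(n) = max(4, n^alpha). At the short series
#' this package handles (<= ~50 points) the maximization is exact: one axis
#' is partitioned into equal-frequency bins and the other axis's partition
#' is optimized exactly by dynamic programming over all cut positions, in
#' both orientations.
#'
#' @param x,y paired numeric observations, at least 8 pairs.
#' @param alpha grid-size exponent, B(n) = n^alpha (default 0.6).
#' @return MIC score in \[0, 1\]; 0 when either variable is constant.
#' @references Reshef et al. (2011) "Detecting novel associations in large
#'   data sets", Science 334:1518-1524.
#' @export
#' @examples
#' x <- seq(0, 1, length.out = 20)
#' mic(x, 2 * x + 1)         # 1: noiseless line
#' mic(x, (x - 0.5)^2)       # ~1: noiseless parabola
mic <- function(x, y, alpha = 0.6) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8) abort("mic() needs at least 8 paired observations")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  B <- max(4, n^alpha)
  best <- 0
  for (swap in c(FALSE, TRUE)) {
    X <- if (swap) y else x
    Y <- if (swap) x else y
    for (b in 2:max(2L, floor(B / 2))) {
      amax <- floor(B / b)
      if (amax < 2) next
      yb <- equifreq_bin(Y, b)
      res <- max_mi_partition(X, yb, b, amax)
      for (a in 2:amax) {
        val <- res[a] / log2(min(a, b))
        if (is.finite(val) && val > best) best <- val
      }
    }
  }
  min(best, 1)
}

# equal-frequency binning into b bins; ties broken by order so bin sizes
# are as equal as possible
equifreq_bin <- function(y, b) {
  n <- length(y)
  r <- rank(y, ties.method = "first")
  pmin(b, 1L + as.integer(floor((r - 1) * b / n)))
}

# For x-partitions into k = 1..amax contiguous intervals (x sorted, tied x
# clumped), return max over partitions of I(X_binned; Y_binned) for each k.
# I = H(Y) - H(Y|X); H(Y|X) is additive over intervals, so exact dynamic
# programming over cut positions applies.
max_mi_partition <- function(X, yb, b, amax) {
  n <- length(X)
  ord <- order(X)
  xo <- X[ord]
  ybo <- yb[ord]
  clump <- cumsum(c(TRUE, diff(xo) > 0))
  m <- clump[n]
  counts <- matrix(0L, m, b)
  for (i in seq_len(n)) {
    counts[clump[i], ybo[i]] <- counts[clump[i], ybo[i]] + 1L
  }
  # prefix[i + 1, ] = column sums of clumps 1..i
  prefix <- rbind(0L, apply(counts, 2L, cumsum))
  if (b == 1L) prefix <- matrix(prefix, ncol = 1L)
  xlog2x <- function(v) ifelse(v > 0, v * log2(v), 0)
  # phi(i, j) = n * H(Y | interval of clumps (i+1)..j)
  phi <- function(i, j) {
    v <- prefix[j + 1L, ] - prefix[i + 1L, ]
    tot <- sum(v)
    xlog2x(tot) - sum(xlog2x(v))
  }
  ytot <- prefix[m + 1L, ]
  Hy <- log2(n) - sum(xlog2x(ytot)) / n
  kmax <- min(amax, m)
  # D[k, j]: min total phi over partitions of clumps 1..j into k intervals
  D <- matrix(Inf, kmax, m)
  for (j in seq_len(m)) D[1L, j] <- phi(0L, j)
  if (kmax >= 2L) {
    for (k in 2:kmax) {
      for (j in k:m) {
        best <- Inf
        for (i in (k - 1L):(j - 1L)) {
          cand <- D[k - 1L, i] + phi(i, j)
          if (cand < best) best <- cand
        }
        D[k, j] <- best
      }
    }
  }
  out <- rep(NA_real_, amax)
  for (k in seq_len(kmax)) out[k] <- Hy - D[k, m] / n
  if (amax > kmax) out[(kmax + 1L):amax] <- out[kmax]
  out
}
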