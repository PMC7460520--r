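# Independent brute-force oracles used to cross-check the implementation.

# Bilinear sample of a matrix at fractional coordinates.
bilinear_at <- function(m, y, x) {
  y0 <- pmax(1, pmin(nrow(m) - 1, floor(y)))
  x0 <- pmax(1, pmin(ncol(m) - 1, floor(x)))
  fy <- y - y0
  fx <- x - x0
  m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    m[cbind(y0 + 1, x0 + 1)] * fy * fx
}

# Exhaustive per-angle scan of the emitted lesion mask against the recorded
# junction truth: recomputes the invasion fraction independently of the
# generator's own bookkeeping.
oracle_invasion_fraction <- function(case) {
  jt <- case$junction_truth
  oi <- case$origin["row"]
  oj <- case$origin["col"]
  radii <- seq(0, nrow(case$uterus_mask), by = 0.1)
  f <- numeric(nrow(jt))
  for (k in seq_len(nrow(jt))) {
    v <- bilinear_at(case$lesion_mask,
                     oi + radii * sin(jt$theta[k]),
                     oj + radii * cos(jt$theta[k]))
    hit <- which(v >= 0.5)
    r_l <- if (length(hit)) radii[max(hit)] else 0
    f[k] <- max(0, r_l - jt$r_junction[k]) /
      max(1e-6, jt$r_serosa[k] - jt$r_junction[k])
  }
  n <- length(f)
  fs <- vapply(seq_len(n), function(i) {
    mean(f[((i + (-2:2) - 1) %% n) + 1])
  }, numeric(1))
  min(1, max(fs))
}

# Pearson chi-square statistic by direct cell-wise summation.
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Random binary mask of given fill probability.
random_mask <- function(n = 24, p = 0.4) {
  matrix(as.numeric(stats::runif(n * n) < p), n, n)
}

# Filled circle mask.
circle_mask <- function(n, cy, cx, r) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  ((rows - cy)^2 + (cols - cx)^2 <= r^2) * 1
}

rotate90 <- function(m) t(m)[, rev(seq_len(nrow(m)))]
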