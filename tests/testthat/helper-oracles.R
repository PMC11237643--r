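# Independent oracles, coded literally (loops, sorts, enumeration) and kept
# separate from the package's vectorized/dynamic-programming paths.

# Step-by-step TMM: reference by 75th-percentile count fraction, pairwise
# zero exclusion, double trim, inverse-binomial-variance weighted mean of M,
# geometric-mean-1 rescaling.
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- rowSums(counts)
  f75 <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    f75[i] <- unname(quantile(counts[i, ], 0.75)) / lib[i]
  }
  ref_i <- which.min(abs(f75 - mean(f75)))
  fac <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    M <- c(); A <- c(); v <- c()
    for (j in seq_len(ncol(counts))) {
      o <- counts[i, j]; r <- counts[ref_i, j]
      if (o > 0 && r > 0) {
        po <- o / lib[i]; pr <- r / lib[ref_i]
        M <- c(M, log2(po / pr))
        A <- c(A, (log2(po) + log2(pr)) / 2)
        v <- c(v, (lib[i] - o) / (lib[i] * o) +
                 (lib[ref_i] - r) / (lib[ref_i] * r))
      }
    }
    if (length(M) == 0) stop("no shared positive attributes")
    if (max(abs(M)) < 1e-6) { fac[i] <- 1; next }
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- which(rM >= loM & rM <= hiM & rA >= loA & rA <= hiA)
    fac[i] <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  fac / exp(mean(log(fac)))
}

# Exhaustive piecewise-constant segmentation: enumerate every admissible
# break combination per candidate break count, then the same BIC rule.
oracle_segment <- function(values, h = 0.01, min_segment = 2, max_breaks = 5) {
  n <- length(values)
  m <- max(min_segment, ceiling(h * n))
  rss_seg <- function(i, j) {
    v <- values[i:j]
    sum((v - mean(v))^2)
  }
  b_max <- max(min(max_breaks, n %/% m - 1), 0)
  rss_b <- rep(Inf, b_max + 1)
  best <- vector("list", b_max + 1)
  for (b in 0:b_max) {
    if (b == 0) {
      rss_b[1] <- rss_seg(1, n)
      best[[1]] <- integer(0)
      next
    }
    for (bp in utils::combn(seq_len(n - 1), b, simplify = FALSE)) {
      bounds <- c(0, bp, n)
      if (any(diff(bounds) < m)) next
      r <- 0
      for (s in seq_len(b + 1)) r <- r + rss_seg(bounds[s] + 1, bounds[s + 1])
      if (r < rss_b[b + 1] - 1e-12) {
        rss_b[b + 1] <- r
        best[[b + 1]] <- bp
      }
    }
  }
  if (rss_b[1] <= 0) {
    chosen <- 0L
  } else {
    bic <- n * log(pmax(rss_b, rss_b[1] * 1e-10) / n) +
      (2 * (0:b_max) + 1) * log(n)
    chosen <- which.min(bic) - 1L
  }
  list(rss = rss_b, n_breaks = chosen, breakpoints = best[[chosen + 1]],
       min_segment_effective = m)
}
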