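#' Structural-change segmentation of an ordered series
#'
#' Fits piecewise-constant (intercept-only) models to a one-dimensional
#' ordered series by exact dynamic programming: for each candidate number of
#' breaks `b = 0..max_breaks` the globally least-squares-optimal break
#' positions are found, subject to a minimum segment length of
#' `max(min_segment, ceiling(h * n))`. The number of breaks is then chosen by
#' BIC over segment residual sums of squares,
#' `BIC(b) = n * log(RSS_b / n) + (2b + 1) * log(n)`
#' (one mean per segment plus one position per break). Sorted importance,
#' abundance, and coefficient-of-variation curves are segmented this way to
#' cut their leading set.
#'
#' Degenerate inputs are not errors: a series too short for any admissible
#' break, or with (numerically) zero variance, yields zero breakpoints.
#' Residual sums of squares equal to zero are floored at a scale-relative
#' epsilon so the BIC comparison stays defined; the selection is invariant to
#' adding a constant to the series and to positive rescaling.
#'
#' @param values Numeric vector, finite; for fingerprint use, sorted
#'   descending (a decay curve).
#' @param labels Optional attribute ids aligned to `values`.
#' @param h Minimum segment length as a fraction of the series length
#'   (default 0.01).
#' @param min_segment Minimum segment length in elements (default 2).
#' @param max_breaks Largest number of breaks scanned (default 5).
#' @return An object of class `fp_segmentation`: a list with `breakpoints`
#'   (indices of the last element of each segment but the final one, possibly
#'   empty), `n_segments`, and `diagnostics`, a tibble with one row per
#'   candidate break count (`n_breaks`, `rss`, `bic`, `chosen`).
#' @examples
#' seg <- segment_series(c(10, 10, 10, 1, 1, 1))
#' seg$breakpoints
#' @export
segment_series <- function(values, labels = NULL, h = 0.01, min_segment = 2L,
                           max_breaks = 5L) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("series values must be finite numbers")
  }
  n <- length(values)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n) abort("labels must align with values")
  m <- max(as.integer(min_segment), as.integer(ceiling(h * n)))
  if (m < 1L) abort("minimum segment length must be >= 1")
  if (n < 2L || n < m) {
    rss0 <- sum((values - mean(values))^2)
    return(structure(
      list(breakpoints = integer(0), n_segments = 1L, labels = labels,
           values = values, min_segment_effective = m,
           diagnostics = tibble::tibble(n_breaks = 0L, rss = rss0,
                                        bic = NA_real_, chosen = TRUE)),
      class = "fp_segmentation"
    ))
  }

  s1p <- c(0, cumsum(values))
  s2p <- c(0, cumsum(values^2))
  # RSS of segment (i..j], i.e. elements (i+1):j, from prefix sums
  seg_rss <- function(i, j) {
    len <- j - i
    s <- s1p[j + 1L] - s1p[i + 1L]
    q <- s2p[j + 1L] - s2p[i + 1L]
    pmax(q - s^2 / len, 0)
  }

  b_max <- min(as.integer(max_breaks), n %/% m - 1L)
  b_max <- max(b_max, 0L)

  # dp[b+1, j]: minimal RSS for prefix 1..j split into b+1 segments
  dp <- matrix(Inf, nrow = b_max + 1L, ncol = n)
  bt <- matrix(NA_integer_, nrow = b_max + 1L, ncol = n)
  js <- m:n
  dp[1L, js] <- seg_rss(0L, js)
  if (b_max >= 1L) {
    for (b in seq_len(b_max)) {
      for (j in seq((b + 1L) * m, n)) {
        t_cand <- seq(b * m, j - m)
        tot <- dp[b, t_cand] + seg_rss(t_cand, j)
        best <- which.min(tot)
        dp[b + 1L, j] <- tot[best]
        bt[b + 1L, j] <- t_cand[best]
      }
    }
  }

  rss_b <- dp[, n]
  rss0 <- rss_b[1]
  floor_eps <- if (rss0 > 0) rss0 * 1e-10 else 0
  if (rss0 <= 0) {
    # constant series: nothing to explain
    chosen_b <- 0L
    bic <- rep(NA_real_, b_max + 1L)
  } else {
    bic <- n * log(pmax(rss_b, floor_eps) / n) +
      (2 * (0:b_max) + 1) * log(n)
    chosen_b <- which.min(bic) - 1L
  }

  breakpoints <- integer(0)
  if (chosen_b > 0L) {
    breakpoints <- integer(chosen_b)
    j <- n
    for (b in seq(chosen_b, 1L)) {
      j <- bt[b + 1L, j]
      breakpoints[b] <- j
    }
  }

  structure(
    list(
      breakpoints = breakpoints,
      n_segments = chosen_b + 1L,
      labels = labels,
      values = values,
      min_segment_effective = m,
      diagnostics = tibble::tibble(
        n_breaks = 0:b_max,
        rss = rss_b,
        bic = bic,
        chosen = 0:b_max == chosen_b
      )
    ),
    class = "fp_segmentation"
  )
}

#' Cut the head of a sorted series at its first breakpoint
#'
#' Returns the labels of the first segment — everything before the first
#' breakpoint of a descending-sorted curve. This is the "leading set" rule:
#' even when the optimal segmentation has several breaks, only the head is
#' extracted. Zero breakpoints yield an empty set with a warning.
#'
#' @param segmentation A [segment_series()] result.
#' @return Character vector of labels (possibly empty).
#' @export
cut_head <- function(segmentation) {
  stopifnot(inherits(segmentation, "fp_segmentation"))
  if (!length(segmentation$breakpoints)) {
    warn("no breakpoint found; returning an empty head set")
    return(character(0))
  }
  segmentation$labels[seq_len(segmentation$breakpoints[1])]
}
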