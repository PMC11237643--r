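#' Trimmed mean of M-values (TMM) scale factors
#'
#' Estimates one relative scale factor per sample so that between-sample
#' comparisons of attribute abundance are not distorted by sequencing depth
#' or by a minority of highly abundant attributes. The procedure:
#'
#' 1. Pick a reference sample: the one whose 75th-percentile count fraction
#'    (upper quartile of counts divided by library size) is closest to the
#'    mean 75th-percentile fraction across samples.
#' 2. For every sample, over attributes with positive counts in both the
#'    sample and the reference (pairwise zero exclusion, no pseudocounts),
#'    compute the log2 fraction ratio M and mean log2 fraction A.
#' 3. Double-trim: drop the most extreme `trim_m` fraction of M values on
#'    each side and the most extreme `trim_a` fraction of A values on each
#'    side.
#' 4. The sample's factor is 2 to the precision-weighted mean of the
#'    remaining M values, weights being inverse approximate binomial
#'    variances of M.
#' 5. Rescale all factors to geometric mean 1.
#'
#' A sample whose M values are all within 1e-6 of zero (e.g. a pure depth
#' rescaling of the reference) gets factor exactly 1 before the final
#' rescaling.
#'
#' @param table A filtered [attr_table()] of raw counts; every sample must
#'   have a positive total.
#' @param trim_m,trim_a Two-sided trim fractions for the M and A dimensions
#'   (defaults 0.30 and 0.05).
#' @return An object of class `tmm_factors`: a tibble with columns `sample`
#'   and `factor`, plus attributes `reference_sample`, `trim_m`, `trim_a`.
#' @seealso [apply_normalization()]
#' @export
compute_tmm_factors <- function(table, trim_m = 0.30, trim_a = 0.05) {
  m <- attr_matrix(table)
  lib <- rowSums(m)
  if (any(lib <= 0)) {
    abort(paste0("sample with zero total count: ",
                 rownames(m)[which(lib <= 0)[1]]))
  }
  # reference: 75th-percentile count fraction closest to the mean across samples
  f75 <- apply(m, 1L, function(x) quantile(x, 0.75, names = FALSE)) / lib
  ref_i <- which.min(abs(f75 - mean(f75)))
  ref <- m[ref_i, ]
  nR <- lib[ref_i]

  fac <- vapply(seq_len(nrow(m)), function(i) {
    obs <- m[i, ]
    nO <- lib[i]
    ok <- obs > 0 & ref > 0
    if (!any(ok)) {
      abort(paste0("sample `", rownames(m)[i],
                   "` shares no positive attributes with the reference `",
                   rownames(m)[ref_i], "`"))
    }
    logR <- log2((obs[ok] / nO) / (ref[ok] / nR))
    absE <- (log2(obs[ok] / nO) + log2(ref[ok] / nR)) / 2
    v <- (nO - obs[ok]) / nO / obs[ok] + (nR - ref[ok]) / nR / ref[ok]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    rM <- rank(logR)
    rA <- rank(absE)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }, numeric(1))

  fac <- fac / exp(mean(log(fac)))
  structure(
    tibble::tibble(sample = rownames(m), factor = fac),
    class = c("tmm_factors", class(tibble::tibble())),
    reference_sample = rownames(m)[ref_i],
    trim_m = trim_m, trim_a = trim_a
  )
}

#' Apply TMM normalization, scaled to counts per million
#'
#' Divides each count by its sample's effective library size (raw total
#' multiplied by the sample's TMM factor) and scales to counts per million.
#' Within-sample rank order of attributes is preserved; doubling every count
#' of a sample leaves its normalized row unchanged.
#'
#' @param table A raw-count [attr_table()].
#' @param factors A [compute_tmm_factors()] result covering all samples of
#'   `table`.
#' @return The normalized attribute table (`normalized = TRUE`).
#' @export
apply_normalization <- function(table, factors) {
  m <- attr_matrix(table)
  idx <- match(rownames(m), factors$sample)
  if (anyNA(idx)) {
    abort(paste0("missing TMM factor for sample `",
                 rownames(m)[which(is.na(idx))[1]], "`"))
  }
  eff <- rowSums(m) * factors$factor[idx]
  norm <- sweep(m, 1L, eff, "/") * 1e6
  attr_table_from_matrix(norm, attribute_type = attribute_type(table),
                         normalized = TRUE)
}

#' One-call normalization pipeline
#'
#' Convenience wrapper: sample filter, attribute filter, TMM factors, CPM
#' scaling.
#'
#' @inheritParams filter_samples
#' @return A normalized [attr_table()]; the `tmm_factors` object is attached
#'   as attribute `"tmm"`.
#' @export
normalize_table <- function(table, config = fp_config()) {
  table <- filter_samples(table, config)
  table <- filter_attributes(table, config)
  fac <- compute_tmm_factors(table, trim_m = config$tmm$trim_m,
                             trim_a = config$tmm$trim_a)
  out <- apply_normalization(table, fac)
  attr(out, "tmm") <- fac
  out
}
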