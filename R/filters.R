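#' Filter samples by total read count
#'
#' Retains samples whose total count strictly exceeds the depth threshold for
#' the table's attribute type: 2000 for KO and Pfam, 500 for TIGRFAM (read
#' counts run lower in that annotation set), 4000 for read-based genera.
#' Sample order is preserved. Idempotent.
#'
#' @param table An unnormalized [attr_table()].
#' @param config An [fp_config()]; thresholds live in
#'   `config$filter$min_sample_reads`.
#' @return The filtered attribute table.
#' @export
filter_samples <- function(table, config = fp_config()) {
  if (is_normalized(table)) abort("filter_samples() expects raw counts")
  thr <- config$filter$min_sample_reads[[attribute_type(table)]]
  totals <- rowSums(attr_matrix(table))
  keep <- totals > thr
  if (!any(keep)) {
    abort(sprintf(
      "no samples exceed %s total reads for type %s (max observed: %s of %d samples)",
      thr, attribute_type(table), max(totals), length(totals)
    ))
  }
  out <- table[keep, , drop = FALSE]
  attr_table(out, attribute_type = attribute_type(table), normalized = FALSE)
}

#' Filter attributes by prevalence or total count
#'
#' An attribute is retained when **either** criterion holds (logical OR):
#' it is non-zero in at least half of the (already sample-filtered) samples —
#' `>= ceiling(min_prevalence_fraction * n_samples)` — or its total count over
#' all samples reaches `min_total_count` (default 7560, an average of 5 reads
#' per sample over 1512 samples). Both comparisons are inclusive. Attribute
#' order is preserved. Idempotent.
#'
#' @inheritParams filter_samples
#' @return The filtered attribute table.
#' @export
filter_attributes <- function(table, config = fp_config()) {
  m <- attr_matrix(table)
  n <- nrow(m)
  need_prev <- ceiling(config$filter$min_prevalence_fraction * n)
  prev <- colSums(m > 0)
  tot <- colSums(m)
  keep <- prev >= need_prev | tot >= config$filter$min_total_count
  if (!any(keep)) {
    abort(sprintf(
      "no attributes retained (prevalence >= %d of %d samples or total >= %s)",
      need_prev, n, config$filter$min_total_count
    ))
  }
  out <- table[, c(TRUE, keep), drop = FALSE]
  attr_table(out, attribute_type = attribute_type(table),
             normalized = is_normalized(table))
}
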