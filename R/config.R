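#' Default pipeline configuration
#'
#' Returns the full parameter set used across the fingerprinting pipeline as a
#' nested list. Every stage of the pipeline reads its tunables from this
#' structure, so a single modified copy reproducibly reconfigures a whole run.
#'
#' The defaults encode the reference analysis conditions:
#' * `filter$min_sample_reads`: per-attribute-type sample depth cutoffs
#'   (strictly greater-than): KO 2000, PFAM 2000, TIGRFAM 500, GENUS 4000.
#' * `filter$min_prevalence_fraction` (0.5) and `filter$min_total_count`
#'   (7560): an attribute is retained when it is non-zero in at least half of
#'   the samples *or* its total count reaches 7560 (an average of 5 reads per
#'   sample over 1512 samples; see [derive_min_total_count()]).
#' * `tmm`: trim fractions for the M (0.30) and A (0.05) dimensions of TMM.
#' * `breakpoint`: minimum segment fraction `h` (0.01), minimum segment size
#'   (2), and the number of breaks scanned for the fingerprint cut (1: the
#'   cut is a two-regime split separating the leading set from the tail;
#'   [segment_series()] itself supports any `max_breaks` for exploratory
#'   multi-regime segmentation, but on smooth decay curves an information
#'   criterion places extra breaks inside the leading region, which would
#'   shrink the head to the steepest top fraction).
#' * `supervised`: extreme-split fraction (0.10) and forest size (500 trees).
#' * `validation`: 10-fold cross-validation repeated 5 times on a 50% train
#'   split, and the model-quality gate (RMSE < 0.8 or variance explained
#'   >= 60%, combined with OR).
#' * `unsupervised`: k scan range (2..12), k-means restarts, regression alpha
#'   (0.05, uncorrected) and the minimum number of significant factor
#'   correlations for a cluster solution to be considered informative.
#'
#' @param ... Named overrides replacing individual entries, e.g.
#'   `fp_config(breakpoint = list(max_breaks = 3))`. Overrides are merged
#'   recursively, so sibling defaults are kept.
#'
#' @return A nested named list with class `"fp_config"`.
#' @examples
#' cfg <- fp_config(supervised = list(n_trees = 100))
#' cfg$supervised$n_trees
#' cfg$filter$min_total_count
#' @export
fp_config <- function(...) {
  defaults <- list(
    filter = list(
      min_sample_reads = c(KO = 2000, PFAM = 2000, TIGRFAM = 500, GENUS = 4000),
      min_prevalence_fraction = 0.5,
      min_total_count = 7560
    ),
    tmm = list(trim_m = 0.30, trim_a = 0.05),
    breakpoint = list(h = 0.01, min_segment = 2L, max_breaks = 1L),
    supervised = list(fraction = 0.10, n_trees = 500L),
    validation = list(
      folds = 10L, repeats = 5L, train_fraction = 0.5, n_trees = 500L,
      gate = list(max_rmse = 0.8, min_variance_explained = 0.60,
                  combination = "OR")
    ),
    unsupervised = list(
      k_range = 2:12, nstart = 10L, alpha = 0.05, min_significant = 3L
    )
  )
  overrides <- list(...)
  cfg <- modify_defaults(defaults, overrides)
  structure(cfg, class = "fp_config")
}

# recursive merge: override leaves, keep untouched siblings
modify_defaults <- function(defaults, overrides) {
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]]))) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Derive the attribute total-count threshold from a per-sample average
#'
#' The attribute retention filter admits any attribute whose total count over
#' all samples reaches `reads_per_sample * n_samples`. With an average of 5
#' reads per sample over the 1512-sample reference compilation this evaluates
#' to 7560, the fixed default in [fp_config()]. Exposing the arithmetic keeps
#' the threshold meaningful on data sets of other sizes.
#'
#' @param reads_per_sample Average read count per sample an attribute must
#'   reach (default 5).
#' @param n_samples Number of samples in the table.
#' @return A single number, `reads_per_sample * n_samples`.
#' @examples
#' derive_min_total_count(5, 1512)
#' @export
derive_min_total_count <- function(reads_per_sample = 5, n_samples) {
  stopifnot(is.numeric(reads_per_sample), reads_per_sample > 0,
            is.numeric(n_samples), n_samples > 0)
  reads_per_sample * n_samples
}
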