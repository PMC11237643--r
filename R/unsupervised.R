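#' Cluster samples by their attribute profiles
#'
#' k-means over a scanned range of k, on standardized log1p-transformed
#' normalized abundances (so a few high-CPM attributes cannot dominate the
#' Euclidean distances). For each candidate k the total within-cluster sum
#' of squares (elbow curve) and mean silhouette width are recorded; the
#' chosen k maximizes the silhouette (smallest k on ties), with the elbow
#' curve kept for inspection.
#'
#' Determinism: samples are put in a canonical (sorted-id) order before
#' seeding, so the solution is invariant to input row order; cluster ids are
#' relabelled 1..k by first occurrence in canonical order.
#'
#' @param table A normalized [attr_table()].
#' @param k_range Candidate numbers of clusters (default 2..12), within
#'   `[2, n_samples - 1]`.
#' @param seed Integer seed; candidate k uses derived seed `seed + k`.
#' @param config An [fp_config()] (`unsupervised$nstart` restarts per k).
#' @return An object of class `fp_clusters`: list with `k` (chosen),
#'   `assignment` (named integer vector in input order), `diagnostics`
#'   (tibble: `k`, `total_within_ss`, `silhouette`, `chosen`), `seed`.
#' @export
cluster_samples <- function(table, k_range = 2:12, seed = 1L,
                            config = fp_config()) {
  m <- attr_matrix(table)
  if (any(k_range < 2L) || any(k_range > nrow(m) - 1L)) {
    abort("k_range must lie within [2, n_samples - 1]")
  }
  x <- log1p(m)
  keep <- apply(x, 2L, sd) > 0
  if (!any(keep)) abort("all attributes constant across samples; clustering undefined")
  x <- scale(x[, keep, drop = FALSE])
  ord <- order(rownames(x))
  x <- x[ord, , drop = FALSE]
  d <- dist(x)
  if (max(d) == 0) abort("all samples identical; clustering undefined")

  diag_rows <- purrr::map_dfr(k_range, function(k) {
    km <- withr::with_seed(seed + k, try_kmeans(x, k, config$unsupervised$nstart))
    sil <- cluster::silhouette(km$cluster, d)
    tibble::tibble(k = k, total_within_ss = km$tot.withinss,
                   silhouette = mean(sil[, "sil_width"]))
  })
  chosen_k <- diag_rows$k[which.max(diag_rows$silhouette)]
  km <- withr::with_seed(seed + chosen_k,
                         try_kmeans(x, chosen_k, config$unsupervised$nstart))
  cl <- relabel_by_first_occurrence(km$cluster)
  names(cl) <- rownames(x)
  assignment <- cl[table$sample]
  structure(
    list(k = chosen_k, assignment = assignment,
         diagnostics = dplyr::mutate(diag_rows, chosen = .data$k == chosen_k),
         seed = seed),
    class = "fp_clusters"
  )
}

# kmeans with retries against empty-cluster convergence failures
try_kmeans <- function(x, k, nstart) {
  for (attempt in seq_len(5L)) {
    km <- tryCatch(
      kmeans(x, centers = k, nstart = nstart, iter.max = 100L),
      error = function(e) e
    )
    if (!inherits(km, "error")) return(km)
  }
  abort(sprintf("k-means failed to converge for k = %d: %s", k,
                conditionMessage(km)))
}

relabel_by_first_occurrence <- function(cl) {
  first <- unique(cl)
  match(cl, first)
}

#' Regress per-sample total abundance on each factor, per cluster
#'
#' For every cluster, the total normalized abundance per sample (the sum
#' over all retained attributes) is regressed on each environmental factor
#' over that cluster's samples by ordinary least squares. Slope, R-squared
#' and p-value are recorded per (cluster, factor); the number of significant
#' factors at `alpha` summarizes how strongly a cluster's microbiomes track
#' coordinated environmental change. Clusters with fewer than 3 samples, and
#' factors constant (or mostly missing) within a cluster, are marked
#' unusable/skipped rather than significant.
#'
#' @param solution A [cluster_samples()] result.
#' @param table The normalized [attr_table()] that was clustered.
#' @param env An [env_table()].
#' @param alpha Per-regression significance level (default 0.05,
#'   uncorrected).
#' @return An object of class `fp_cluster_profiles`: list with `regressions`
#'   (tibble: `cluster`, `factor`, `n`, `slope`, `r_squared`, `p_value`,
#'   `significant`) and `summary` (tibble: `cluster`, `n_samples`, `usable`,
#'   `n_significant`, `mean_r2_significant`), plus `alpha`.
#' @export
profile_clusters <- function(solution, table, env, alpha = 0.05) {
  al <- align_samples_quiet(table, env)
  totals <- rowSums(attr_matrix(al$table))
  assignment <- solution$assignment[al$table$sample]
  if (anyNA(assignment)) abort("cluster solution does not cover all table samples")
  factors <- intersect(env_factor_names(), names(al$env))

  regressions <- purrr::map_dfr(sort(unique(assignment)), function(cl) {
    in_cl <- assignment == cl
    purrr::map_dfr(factors, function(f) {
      x <- al$env[[f]][in_cl]
      y <- totals[in_cl]
      ok <- !is.na(x)
      base <- tibble::tibble(cluster = cl, factor = f, n = sum(ok),
                             slope = NA_real_, r_squared = NA_real_,
                             p_value = NA_real_, significant = FALSE)
      if (sum(in_cl) < 3L || sum(ok) < 3L || sd(x[ok]) == 0) return(base)
      fit <- summary(lm(y[ok] ~ x[ok]))
      base$slope <- fit$coefficients[2, 1]
      base$r_squared <- fit$r.squared
      base$p_value <- fit$coefficients[2, 4]
      base$significant <- is.finite(base$p_value) && base$p_value < alpha
      base
    })
  })
  summary_tbl <- regressions |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_significant = sum(.data$significant),
      mean_r2_significant = ifelse(any(.data$significant),
                                   mean(.data$r_squared[.data$significant]), 0),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      tibble::tibble(cluster = as.integer(names(table(assignment))),
                     n_samples = as.integer(table(assignment))),
      by = "cluster"
    ) |>
    dplyr::mutate(usable = .data$n_samples >= 3L) |>
    dplyr::select("cluster", "n_samples", "usable", "n_significant",
                  "mean_r2_significant")
  structure(list(regressions = regressions, summary = summary_tbl,
                 alpha = alpha),
            class = "fp_cluster_profiles")
}

#' Select the cluster most strongly tracking the environment
#'
#' Picks the usable cluster with the largest number of significant factor
#' correlations; ties are broken by the highest mean R-squared over the
#' significant factors. Both criteria are logged.
#'
#' @param profiles A [profile_clusters()] result.
#' @return The selected cluster id (integer).
#' @export
select_cluster <- function(profiles) {
  stopifnot(inherits(profiles, "fp_cluster_profiles"))
  s <- dplyr::filter(profiles$summary, .data$usable)
  if (!nrow(s)) abort("no usable cluster (all have < 3 samples)")
  s <- dplyr::arrange(s, dplyr::desc(.data$n_significant),
                      dplyr::desc(.data$mean_r2_significant), .data$cluster)
  inform(sprintf(
    "selected cluster %d: %d significant factor correlation(s), mean R2 %.3f",
    s$cluster[1], s$n_significant[1], s$mean_r2_significant[1]
  ))
  as.integer(s$cluster[1])
}

#' Most-abundant and most-variable attribute fingerprints of a cluster
#'
#' Restricted to the selected cluster's samples, attributes are sorted by
#' descending total normalized abundance, and separately by descending
#' coefficient of variation (sd/mean; attributes with zero mean excluded —
#' a constant attribute has CV 0 and can never lead the curve). Each sorted
#' curve is cut at its first structural-change breakpoint; the two head sets
#' are the cluster's fingerprints. Ties in either sort order are broken by
#' attribute id, so results are invariant to column order.
#'
#' @param table The normalized [attr_table()] that was clustered.
#' @param solution A [cluster_samples()] result.
#' @param cluster The selected cluster id.
#' @param config An [fp_config()] (breakpoint parameters).
#' @return An object of class `fp_cluster_fp`: list with `cluster`,
#'   `abundant_members` (tibble: `attribute_id`, `total_abundance`),
#'   `variable_members` (tibble: `attribute_id`, `cv`), and the two
#'   segmentations.
#' @export
extract_cluster_fingerprint <- function(table, solution, cluster,
                                        config = fp_config()) {
  in_cl <- names(solution$assignment)[solution$assignment == cluster]
  if (!length(in_cl)) abort(sprintf("cluster %s has no samples", cluster))
  m <- attr_matrix(table)[in_cl, , drop = FALSE]
  bp <- config$breakpoint

  tot <- colSums(m)
  ord_a <- order(-tot, colnames(m))
  seg_a <- segment_series(tot[ord_a], labels = colnames(m)[ord_a],
                          h = bp$h, min_segment = bp$min_segment,
                          max_breaks = bp$max_breaks)
  abundant <- cut_head_quiet(seg_a)

  mu <- colMeans(m)
  sds <- apply(m, 2L, sd)
  ok <- mu > 0
  cv <- sds[ok] / mu[ok]
  ord_v <- order(-cv, names(cv))
  seg_v <- segment_series(cv[ord_v], labels = names(cv)[ord_v],
                          h = bp$h, min_segment = bp$min_segment,
                          max_breaks = bp$max_breaks)
  variable <- cut_head_quiet(seg_v)

  structure(
    list(
      cluster = as.integer(cluster),
      abundant_members = tibble::tibble(attribute_id = abundant,
                                        total_abundance = tot[abundant]),
      variable_members = tibble::tibble(attribute_id = variable,
                                        cv = cv[variable]),
      segmentation_abundance = seg_a,
      segmentation_cv = seg_v
    ),
    class = "fp_cluster_fp"
  )
}

cut_head_quiet <- function(seg) {
  if (!length(seg$breakpoints)) {
    warn("no breakpoint found; fingerprint member set is empty")
    return(character(0))
  }
  seg$labels[seq_len(seg$breakpoints[1])]
}

#' Full unsupervised pipeline
#'
#' Clusters the samples, profiles every cluster against the environmental
#' factors, selects the most environment-coupled cluster, and extracts its
#' abundant/variable fingerprints. When even the best cluster has fewer
#' significant factor correlations than `config$unsupervised$min_significant`
#' the solution is flagged as uninformative (`informative = FALSE`), but the
#' selection statistics are still reported.
#'
#' @inheritParams cluster_samples
#' @param env An [env_table()].
#' @return An object of class `fp_unsupervised`: list with `clusters`,
#'   `profiles`, `selected_cluster`, `informative`, `fingerprint`.
#' @export
fp_unsupervised <- function(table, env, config = fp_config(), seed = 1L) {
  al <- align_samples_quiet(table, env)
  cl <- cluster_samples(al$table, k_range = config$unsupervised$k_range,
                        seed = seed, config = config)
  prof <- profile_clusters(cl, al$table, al$env,
                           alpha = config$unsupervised$alpha)
  sel <- select_cluster(prof)
  n_sig <- prof$summary$n_significant[prof$summary$cluster == sel]
  informative <- n_sig >= config$unsupervised$min_significant
  if (!informative) {
    warn(sprintf(
      "best cluster has only %d significant factor correlation(s) (< %d); solution flagged uninformative",
      n_sig, config$unsupervised$min_significant
    ))
  }
  fp <- extract_cluster_fingerprint(al$table, cl, sel, config = config)
  structure(
    list(clusters = cl, profiles = prof, selected_cluster = sel,
         informative = informative, fingerprint = fp),
    class = "fp_unsupervised"
  )
}
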