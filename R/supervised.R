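#' Split samples into extreme deciles of an environmental factor
#'
#' Forms the two contrast groups for supervised fingerprinting: the samples
#' with the lowest and highest `fraction` (default 10%) of values of one
#' environmental factor. Samples missing the factor are excluded before
#' ranking. Each group has exactly `floor(fraction * n)` members; ties are
#' broken deterministically by a stable sort on (value, sample id).
#'
#' @param env An [env_table()].
#' @param factor Name of the factor column to split on.
#' @param fraction Tail fraction per group (default 0.10).
#' @return An object of class `fp_split`: list with `factor`, `low_ids`,
#'   `high_ids`, `fraction`, `n_used`.
#' @export
split_extremes <- function(env, factor, fraction = 0.10) {
  if (!factor %in% names(env)) abort(paste0("factor `", factor, "` not in metadata"))
  usable <- env[!is.na(env[[factor]]), c("sample", factor)]
  n <- nrow(usable)
  if (n < 20L) {
    abort(sprintf("factor `%s`: only %d samples with values; need >= 20", factor, n))
  }
  v <- usable[[factor]]
  if (max(v) == min(v)) {
    abort(paste0("factor `", factor, "` has no variation; extremes undefined"))
  }
  k <- floor(fraction * n)
  if (k < 2L) abort(sprintf("factor `%s`: group size %d < 2", factor, k))
  asc <- usable$sample[order(v, usable$sample)]
  desc <- usable$sample[order(-v, usable$sample)]
  low <- asc[seq_len(k)]
  high <- desc[seq_len(k)]
  if (length(intersect(low, high))) {
    abort(paste0("factor `", factor, "` extremes overlap; too many ties"))
  }
  structure(
    list(factor = factor, low_ids = low, high_ids = high,
         fraction = fraction, n_used = n),
    class = "fp_split"
  )
}

#' Rank attributes by random-forest permutation importance
#'
#' Fits a random forest classifying the contrast groups (low/high extreme
#' deciles, one biome vs. the rest, or any supplied label vector — a
#' multi-class biome model is obtained by passing the biome column directly)
#' and scores each attribute by permutation importance: the mean decrease in
#' out-of-bag prediction quality when that attribute is permuted, divided by
#' its standard error. Deterministic given `seed` (single-threaded forest).
#'
#' @param table A normalized [attr_table()].
#' @param groups An [split_extremes()] result, or a vector of class labels
#'   named by (or aligned to) `table$sample`.
#' @param seed Integer seed for the forest.
#' @param n_trees Number of trees (default 500).
#' @return An object of class `fp_importance`: a tibble with columns
#'   `attribute_id` and `importance`, sorted by descending importance (ties
#'   broken by attribute id).
#' @export
rank_importance <- function(table, groups, seed = 1L, n_trees = 500L) {
  m <- attr_matrix(table)
  if (inherits(groups, "fp_split")) {
    ids <- sort(c(groups$low_ids, groups$high_ids))  # canonical row order
    missing_ids <- setdiff(ids, rownames(m))
    if (length(missing_ids)) {
      abort(paste0("split samples absent from table: ",
                   paste(head(missing_ids, 3), collapse = ", ")))
    }
    y <- factor(ifelse(ids %in% groups$low_ids, "low", "high"),
                levels = c("low", "high"))
    m <- m[ids, , drop = FALSE]
  } else {
    labels <- groups
    if (!is.null(names(labels))) {
      labels <- labels[rownames(m)]
    } else if (length(labels) != nrow(m)) {
      abort("group labels must align with table samples")
    }
    keep <- !is.na(labels)
    y <- factor(labels[keep])
    m <- m[keep, , drop = FALSE]
  }
  if (any(table(y) < 2L)) abort("each group needs at least 2 samples")
  fit <- ranger::ranger(
    x = m, y = y,
    num.trees = n_trees,
    importance = "permutation",
    scale.permutation.importance = TRUE,
    seed = seed,
    num.threads = 1
  )
  imp <- fit$variable.importance
  out <- tibble::tibble(attribute_id = names(imp), importance = unname(imp))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance), .data$attribute_id)
  structure(out, class = c("fp_importance", class(tibble::tibble())),
            seed = seed, n_trees = n_trees)
}

#' Extract the signed genomic fingerprint for one factor or biome
#'
#' The supervised ("approach i") pipeline for a single context:
#'
#' 1. Label samples — extreme deciles for an environmental factor
#'   ([split_extremes()]), or one-vs-rest for a biome.
#' 2. Rank all attributes by forest permutation importance
#'   ([rank_importance()]).
#' 3. Cut the head of the descending importance curve at its first
#'   structural-change breakpoint ([segment_series()], [cut_head()]).
#' 4. Regress each head attribute's normalized abundance on the factor value
#'   (or biome indicator) over **all** usable samples by ordinary least
#'   squares, and sign the fingerprint: positive slope means association with
#'   high factor values, negative with low.
#'
#' Zero-variance attributes are excluded from the regressions and are never
#' members. Negating the factor swaps the high and low member sets exactly.
#'
#' @param table A normalized [attr_table()].
#' @param env An [env_table()] aligned (or alignable) to `table`.
#' @param factor An environmental factor name, or `NULL` when `biome` given.
#' @param biome A biome label for one-vs-rest fingerprinting, or `NULL`.
#' @param config An [fp_config()].
#' @param seed Integer seed (forest).
#' @return An object of class `fp_fingerprint`: list with `context`,
#'   `context_type`, `high_members` / `low_members` (tibbles with columns
#'   `attribute_id`, `importance`, `slope`, `correlation`), `importance`
#'   (the full [rank_importance()] profile), `segmentation`, `head_size`,
#'   `config`, `seed`.
#' @export
fingerprint_context <- function(table, env, factor = NULL, biome = NULL,
                                config = fp_config(), seed = 1L) {
  if (is.null(factor) == is.null(biome)) {
    abort("supply exactly one of `factor` or `biome`")
  }
  al <- align_samples_quiet(table, env)
  table <- al$table; env <- al$env
  m <- attr_matrix(table)

  if (!is.null(factor)) {
    split <- split_extremes(env, factor, fraction = config$supervised$fraction)
    prof <- rank_importance(table, split, seed = seed,
                            n_trees = config$supervised$n_trees)
    usable <- !is.na(env[[factor]])
    x <- env[[factor]][usable]
    context <- factor; context_type <- "factor"
  } else {
    if (!"biome" %in% names(env)) abort("metadata has no `biome` column")
    usable <- !is.na(env$biome)
    if (!biome %in% env$biome[usable]) {
      abort(paste0("biome `", biome, "` not present in metadata"))
    }
    labels <- ifelse(env$biome[usable] == biome, "in", "out")
    names(labels) <- env$sample[usable]
    prof <- rank_importance(
      attr_table(table[usable, , drop = FALSE],
                 attribute_type = attribute_type(table),
                 normalized = is_normalized(table)),
      labels, seed = seed, n_trees = config$supervised$n_trees
    )
    x <- as.numeric(env$biome[usable] == biome)
    context <- biome; context_type <- "biome"
  }

  seg <- segment_series(prof$importance, labels = prof$attribute_id,
                        h = config$breakpoint$h,
                        min_segment = config$breakpoint$min_segment,
                        max_breaks = config$breakpoint$max_breaks)
  head_ids <- cut_head(seg)

  members <- regress_members(m[usable, , drop = FALSE], x, head_ids, prof)
  structure(
    list(
      context = context, context_type = context_type,
      high_members = dplyr::filter(members, .data$slope > 0),
      low_members = dplyr::filter(members, .data$slope < 0),
      importance = prof, segmentation = seg,
      head_size = length(head_ids),
      config = config, seed = seed
    ),
    class = "fp_fingerprint"
  )
}

# OLS slope + Pearson correlation of each head attribute on x, all samples
regress_members <- function(m, x, head_ids, prof) {
  empty <- tibble::tibble(attribute_id = character(), importance = double(),
                          slope = double(), correlation = double())
  if (!length(head_ids)) return(empty)
  y <- m[, head_ids, drop = FALSE]
  sdy <- apply(y, 2L, sd)
  keep <- sdy > 0
  if (!any(keep)) return(empty)
  y <- y[, keep, drop = FALSE]
  vx <- var(x)
  if (vx == 0) return(empty)
  slope <- as.vector(crossprod(x - mean(x), sweep(y, 2L, colMeans(y))) /
                       (vx * (length(x) - 1)))
  corr <- as.vector(cor(x, y))
  out <- tibble::tibble(
    attribute_id = colnames(y),
    importance = prof$importance[match(colnames(y), prof$attribute_id)],
    slope = slope, correlation = corr
  )
  dplyr::arrange(out, dplyr::desc(.data$importance), .data$attribute_id)
}

# align without the per-call message (internal reuse)
align_samples_quiet <- function(table, env) {
  withCallingHandlers(
    align_samples(table, env),
    message = function(m) invokeRestart("muffleMessage")
  )
}

#' Full supervised pipeline for one factor: gate, then fingerprint
#'
#' Runs the repeated cross-validation harness ([cross_validate()]), applies
#' the model-quality gate ([passes_gate()]), and — when the gate passes —
#' extracts the signed fingerprint ([fingerprint_context()]). Contexts whose
#' forest model fails the gate yield no fingerprint, mirroring the treatment
#' of weakly predictable factors.
#'
#' @inheritParams fingerprint_context
#' @param gate Apply the quality gate (default `TRUE`); `FALSE` always
#'   fingerprints.
#' @return An object of class `fp_supervised`: list with `cv`
#'   (a [cross_validate()] result), `gate_passed`, and `fingerprint`
#'   (`NULL` when gated out).
#' @export
fp_supervised <- function(table, env, factor, config = fp_config(),
                          seed = 1L, gate = TRUE) {
  cv <- cross_validate(table, env, factor, seed = seed, config = config)
  ok <- passes_gate(cv, config$validation$gate)
  fp <- NULL
  if (ok || !gate) {
    fp <- fingerprint_context(table, env, factor = factor, config = config,
                              seed = seed)
  } else {
    warn(sprintf("factor `%s` failed the model-quality gate; no fingerprint extracted",
                 factor))
  }
  structure(list(cv = cv, gate_passed = ok, fingerprint = fp),
            class = "fp_supervised")
}
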