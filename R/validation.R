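#' Repeated cross-validation of a forest model for one factor
#'
#' Measures how well the normalized attribute profile predicts an
#' environmental factor, producing the statistics the model-quality gate
#' decides on. Per repeat, the usable samples are split 50/50 into training
#' and test halves; a 10-fold cross-validation within the training half
#' selects the forest's feature-subsampling width `mtry` over the standard
#' three-point grid spanning 2..p (per-fold scores for the selected model
#' are reported), and the gate statistics — root mean square error and
#' variance explained — come from the held-out test half. The response is
#' z-scored over all usable samples first, so RMSE is comparable across
#' factors with different units.
#'
#' @param table A normalized [attr_table()].
#' @param env An [env_table()].
#' @param factor Factor column to predict.
#' @param seed Integer; repeat r uses derived seed `seed + r`.
#' @param config An [fp_config()]; `config$validation` holds folds (10),
#'   repeats (5), train fraction (0.5) and forest size.
#' @return An object of class `fp_cv`: list with `context`, `rmse` and
#'   `variance_explained` (means over repeats, on the standardized response),
#'   `folds`, `repeats`, `train_fraction`, `standardized = TRUE`,
#'   `per_repeat` (test-half scores) and `per_fold`
#'   (`folds * repeats` rows of within-training fold scores).
#' @export
cross_validate <- function(table, env, factor, seed = 1L, config = fp_config()) {
  vc <- config$validation
  al <- align_samples_quiet(table, env)
  m <- attr_matrix(al$table)
  usable <- !is.na(al$env[[factor]])
  m <- m[usable, , drop = FALSE]
  y_raw <- al$env[[factor]][usable]
  n <- length(y_raw)
  if (n < 20L) abort(sprintf("factor `%s`: only %d usable samples; need >= 20", factor, n))
  if (sd(y_raw) == 0) abort(paste0("factor `", factor, "` has zero variance"))
  y <- as.vector(scale(y_raw))

  p <- ncol(m)
  mtry_grid <- unique(pmin(pmax(floor(seq(2, p, length.out = 3)), 1), p))

  fit_score <- function(tr, te, fit_seed, mtry) {
    fit <- ranger::ranger(x = m[tr, , drop = FALSE], y = y[tr],
                          num.trees = vc$n_trees, mtry = mtry,
                          seed = fit_seed, num.threads = 1)
    pred <- predict(fit, data = m[te, , drop = FALSE],
                    num.threads = 1)$predictions
    resid <- y[te] - pred
    c(rmse = sqrt(mean(resid^2)),
      r2 = 1 - sum(resid^2) / sum((y[te] - mean(y[te]))^2))
  }

  per_repeat <- vector("list", vc$repeats)
  per_fold <- vector("list", vc$repeats)
  for (r in seq_len(vc$repeats)) {
    rs <- seed + r
    withr::with_seed(rs, {
      tr <- sort(sample.int(n, round(vc$train_fraction * n)))
      te <- setdiff(seq_len(n), tr)
      folds <- sample(rep_len(seq_len(vc$folds), length(tr)))
    })
    # inner CV: score every candidate mtry on every training fold
    fold_sc <- purrr::map_dfr(mtry_grid, function(mt) {
      purrr::map_dfr(seq_len(vc$folds), function(f) {
        in_fold <- tr[folds == f]
        sc <- fit_score(setdiff(tr, in_fold), in_fold, rs, mt)
        tibble::tibble(mtry = mt, repeat_id = r, fold = f,
                       rmse = sc[["rmse"]], variance_explained = sc[["r2"]])
      })
    })
    cv_mean <- fold_sc |>
      dplyr::group_by(.data$mtry) |>
      dplyr::summarise(rmse = mean(.data$rmse), .groups = "drop")
    best_mtry <- cv_mean$mtry[which.min(cv_mean$rmse)]
    test_sc <- fit_score(tr, te, rs, best_mtry)
    per_repeat[[r]] <- tibble::tibble(repeat_id = r, mtry = best_mtry,
                                      rmse = test_sc[["rmse"]],
                                      variance_explained = test_sc[["r2"]])
    per_fold[[r]] <- dplyr::select(
      dplyr::filter(fold_sc, .data$mtry == best_mtry),
      "repeat_id", "fold", "rmse", "variance_explained"
    )
  }
  per_repeat <- dplyr::bind_rows(per_repeat)
  per_fold <- dplyr::bind_rows(per_fold)
  structure(
    list(
      context = factor,
      rmse = mean(per_repeat$rmse),
      variance_explained = mean(per_repeat$variance_explained),
      folds = vc$folds, repeats = vc$repeats,
      train_fraction = vc$train_fraction,
      standardized = TRUE,
      per_repeat = per_repeat, per_fold = per_fold,
      seed = seed
    ),
    class = "fp_cv"
  )
}

#' Model-quality gate
#'
#' Decides whether a context's forest model is good enough to fingerprint:
#' RMSE (on the standardized response) strictly below `max_rmse` (0.8),
#' **or** variance explained of at least `min_variance_explained` (0.60).
#' The combination is OR by default; set `combination = "AND"` in the policy
#' for the stricter reading. The decision and both statistics are logged.
#'
#' @param result An [cross_validate()] result.
#' @param policy A list with `max_rmse`, `min_variance_explained`,
#'   `combination`; defaults to `fp_config()$validation$gate`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' \dontrun{
#' passes_gate(cv)  # rmse 0.5, varexpl 0.3 -> TRUE via the RMSE branch
#' }
#' @export
passes_gate <- function(result, policy = fp_config()$validation$gate) {
  stopifnot(inherits(result, "fp_cv"))
  a <- result$rmse < policy$max_rmse
  b <- result$variance_explained >= policy$min_variance_explained
  ok <- if (identical(policy$combination, "AND")) a && b else a || b
  inform(sprintf(
    "gate [%s]: rmse=%.3f (< %.2f: %s) %s varexpl=%.3f (>= %.2f: %s) -> %s",
    result$context, result$rmse, policy$max_rmse, a,
    if (identical(policy$combination, "AND")) "AND" else "OR",
    result$variance_explained, policy$min_variance_explained, b, ok
  ))
  ok
}
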