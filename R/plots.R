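#' Plot methods for soilfp results
#'
#' ggplot2 `autoplot()` methods: the importance decay curve with its
#' breakpoint cut, elbow/silhouette diagnostics of the k scan, per-fold
#' cross-validation scores against the gate thresholds, and signed
#' fingerprint members.
#'
#' @param object A soilfp result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name soilfp-plots
NULL

#' @rdname soilfp-plots
#' @method autoplot fp_segmentation
#' @export
autoplot.fp_segmentation <- function(object, ...) {
  df <- tibble::tibble(rank = seq_along(object$values), value = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank", y = "value",
                  title = sprintf("Segmentation: %d segment(s)", object$n_segments)) +
    ggplot2::theme_minimal()
  if (length(object$breakpoints)) {
    p <- p + ggplot2::geom_vline(xintercept = object$breakpoints + 0.5,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @rdname soilfp-plots
#' @method autoplot fp_importance
#' @export
autoplot.fp_importance <- function(object, ...) {
  df <- tibble::tibble(rank = seq_len(nrow(object)),
                       importance = object$importance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$importance)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "attribute rank", y = "permutation importance (scaled)",
                  title = "Importance decay curve") +
    ggplot2::theme_minimal()
}

#' @rdname soilfp-plots
#' @method autoplot fp_fingerprint
#' @export
autoplot.fp_fingerprint <- function(object, ...) {
  df <- tidy(object)
  if (!nrow(df)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = sprintf("%s: empty fingerprint", object$context)))
  }
  df$attribute_id <- stats::reorder(df$attribute_id, df$correlation)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$correlation, y = .data$attribute_id,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Pearson correlation with factor", y = NULL,
                  title = sprintf("Signed fingerprint: %s", object$context)) +
    ggplot2::theme_minimal()
}

#' @rdname soilfp-plots
#' @method autoplot fp_clusters
#' @export
autoplot.fp_clusters <- function(object, ...) {
  df <- tidyr::pivot_longer(object$diagnostics,
                            c("total_within_ss", "silhouette"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(title = sprintf("k scan (chosen k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' @rdname soilfp-plots
#' @param gate Gate policy to draw as reference lines (default
#'   `fp_config()$validation$gate`).
#' @method autoplot fp_cv
#' @export
autoplot.fp_cv <- function(object, gate = fp_config()$validation$gate, ...) {
  df <- tidyr::pivot_longer(object$per_fold, c("rmse", "variance_explained"),
                            names_to = "metric", values_to = "value")
  ref <- tibble::tibble(metric = c("rmse", "variance_explained"),
                        value = c(gate$max_rmse, gate$min_variance_explained))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$repeat_id), y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "repeat", y = NULL,
                  title = sprintf("Cross-validation: %s", object$context)) +
    ggplot2::theme_minimal()
}

#' @rdname soilfp-plots
#' @method autoplot fp_cluster_profiles
#' @export
autoplot.fp_cluster_profiles <- function(object, ...) {
  df <- dplyr::filter(object$regressions, !is.na(.data$r_squared))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$r_squared,
                                   shape = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(y = expression(R^2),
                  title = "Per-cluster environment regressions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
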