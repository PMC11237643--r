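#' Broom-style tidiers for soilfp result objects
#'
#' `tidy()` returns the per-member / per-unit table of a result; `glance()`
#' returns a one-row summary.
#'
#' @param x A soilfp result object.
#' @param ... Unused.
#' @return A tibble.
#' @name soilfp-tidiers
NULL

#' @rdname soilfp-tidiers
#' @method tidy fp_fingerprint
#' @export
tidy.fp_fingerprint <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$high_members, direction = "high"),
    dplyr::mutate(x$low_members, direction = "low")
  ) |>
    dplyr::mutate(context = x$context, .before = 1)
}

#' @rdname soilfp-tidiers
#' @method glance fp_fingerprint
#' @export
glance.fp_fingerprint <- function(x, ...) {
  tibble::tibble(
    context = x$context, context_type = x$context_type,
    head_size = x$head_size,
    n_high = nrow(x$high_members), n_low = nrow(x$low_members),
    n_breakpoints = length(x$segmentation$breakpoints),
    seed = x$seed
  )
}

#' @rdname soilfp-tidiers
#' @method tidy fp_cv
#' @export
tidy.fp_cv <- function(x, ...) x$per_fold

#' @rdname soilfp-tidiers
#' @method glance fp_cv
#' @export
glance.fp_cv <- function(x, ...) {
  tibble::tibble(
    context = x$context, rmse = x$rmse,
    variance_explained = x$variance_explained,
    folds = x$folds, repeats = x$repeats,
    train_fraction = x$train_fraction, standardized = x$standardized
  )
}

#' @rdname soilfp-tidiers
#' @method tidy fp_clusters
#' @export
tidy.fp_clusters <- function(x, ...) x$diagnostics

#' @rdname soilfp-tidiers
#' @method glance fp_clusters
#' @export
glance.fp_clusters <- function(x, ...) {
  chosen <- dplyr::filter(x$diagnostics, .data$chosen)
  tibble::tibble(k = x$k, silhouette = chosen$silhouette,
                 total_within_ss = chosen$total_within_ss, seed = x$seed)
}

#' @rdname soilfp-tidiers
#' @method tidy fp_cluster_profiles
#' @export
tidy.fp_cluster_profiles <- function(x, ...) x$regressions

#' @rdname soilfp-tidiers
#' @method glance fp_cluster_profiles
#' @export
glance.fp_cluster_profiles <- function(x, ...) x$summary

#' @rdname soilfp-tidiers
#' @method tidy fp_cluster_fp
#' @export
tidy.fp_cluster_fp <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(
      dplyr::rename(x$abundant_members, statistic = "total_abundance"),
      direction = "abundant"
    ),
    dplyr::mutate(dplyr::rename(x$variable_members, statistic = "cv"),
                  direction = "variable")
  ) |>
    dplyr::mutate(cluster = x$cluster, .before = 1)
}

#' @rdname soilfp-tidiers
#' @method tidy fp_segmentation
#' @export
tidy.fp_segmentation <- function(x, ...) x$diagnostics

#' @rdname soilfp-tidiers
#' @method glance fp_segmentation
#' @export
glance.fp_segmentation <- function(x, ...) {
  tibble::tibble(
    n_segments = x$n_segments,
    first_breakpoint = if (length(x$breakpoints)) x$breakpoints[1] else NA_integer_,
    min_segment_effective = x$min_segment_effective
  )
}

#' @rdname soilfp-tidiers
#' @method tidy fp_supervised
#' @export
tidy.fp_supervised <- function(x, ...) {
  if (is.null(x$fingerprint)) {
    tibble::tibble(context = x$cv$context, attribute_id = character(),
                   importance = double(), slope = double(),
                   correlation = double(), direction = character())[0, ]
  } else {
    tidy(x$fingerprint)
  }
}

#' @rdname soilfp-tidiers
#' @method glance fp_supervised
#' @export
glance.fp_supervised <- function(x, ...) {
  dplyr::mutate(glance(x$cv), gate_passed = x$gate_passed,
                n_members = if (is.null(x$fingerprint)) 0L else
                  nrow(x$fingerprint$high_members) + nrow(x$fingerprint$low_members))
}

#' @rdname soilfp-tidiers
#' @method tidy fp_unsupervised
#' @export
tidy.fp_unsupervised <- function(x, ...) tidy(x$fingerprint)

#' @rdname soilfp-tidiers
#' @method glance fp_unsupervised
#' @export
glance.fp_unsupervised <- function(x, ...) {
  s <- dplyr::filter(x$profiles$summary, .data$cluster == x$selected_cluster)
  tibble::tibble(
    k = x$clusters$k, selected_cluster = x$selected_cluster,
    n_significant = s$n_significant,
    mean_r2_significant = s$mean_r2_significant,
    informative = x$informative,
    n_abundant = nrow(x$fingerprint$abundant_members),
    n_variable = nrow(x$fingerprint$variable_members)
  )
}

#' Convert fingerprints to writable reports
#'
#' Maps a supervised or cluster fingerprint onto a list of [fp_report()]
#' objects (one per direction) ready for [write_fingerprint_report()].
#'
#' @param x An `fp_fingerprint` or `fp_cluster_fp`.
#' @param parameters Parameter snapshot to embed (default: the object's
#'   config where available).
#' @return A list of `fp_report`s.
#' @export
as_fp_reports <- function(x, parameters = NULL) {
  if (inherits(x, "fp_fingerprint")) {
    pars <- parameters %||% unclass(x$config)
    list(
      fp_report(x$context, "high", x$high_members, parameters = pars),
      fp_report(x$context, "low", x$low_members, parameters = pars)
    )
  } else if (inherits(x, "fp_cluster_fp")) {
    pars <- parameters %||% list()
    list(
      fp_report(paste0("cluster_", x$cluster), "abundant",
                x$abundant_members, parameters = pars),
      fp_report(paste0("cluster_", x$cluster), "variable",
                x$variable_members, parameters = pars)
    )
  } else {
    abort("as_fp_reports() supports fp_fingerprint and fp_cluster_fp objects")
  }
}

#' @method print fp_fingerprint
#' @export
print.fp_fingerprint <- function(x, ...) {
  cat(sprintf("<fp_fingerprint> %s (%s): head %d -> %d high / %d low members\n",
              x$context, x$context_type, x$head_size,
              nrow(x$high_members), nrow(x$low_members)))
  invisible(x)
}

#' @method print fp_cv
#' @export
print.fp_cv <- function(x, ...) {
  cat(sprintf(
    "<fp_cv> %s: rmse %.3f, variance explained %.3f (%d-fold x %d repeats, standardized response)\n",
    x$context, x$rmse, x$variance_explained, x$folds, x$repeats))
  invisible(x)
}

#' @method print fp_clusters
#' @export
print.fp_clusters <- function(x, ...) {
  cat(sprintf("<fp_clusters> chosen k = %d by silhouette over k in {%s}\n",
              x$k, paste(range(x$diagnostics$k), collapse = "..")))
  invisible(x)
}

#' @method print fp_segmentation
#' @export
print.fp_segmentation <- function(x, ...) {
  cat(sprintf("<fp_segmentation> %d segment(s); breakpoints: %s\n",
              x$n_segments,
              if (length(x$breakpoints)) paste(x$breakpoints, collapse = ", ")
              else "none"))
  invisible(x)
}
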