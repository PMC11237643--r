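#' Construct an attribute table
#'
#' An attribute table is the unit of all downstream computation: a tibble with
#' a first column `sample` (unique sample identifiers) and one numeric column
#' per microbial attribute (a KEGG orthology, Pfam or TIGRFAM family, or a
#' read-based genus). The attribute type is carried as metadata because it
#' determines which filter thresholds apply.
#'
#' @param x A data frame with a `sample` first column and numeric attribute
#'   columns.
#' @param attribute_type One of `"KO"`, `"PFAM"`, `"TIGRFAM"`, `"GENUS"`.
#' @param normalized Logical; `FALSE` for raw integer counts, `TRUE` after
#'   [apply_normalization()].
#' @return A tibble of class `fp_attr_tbl` with attributes `attribute_type`
#'   and `normalized`.
#' @examples
#' attr_table(
#'   data.frame(sample = c("s1", "s2"), K00001 = c(3, 0), K00002 = c(1, 9)),
#'   attribute_type = "KO"
#' )
#' @export
attr_table <- function(x, attribute_type = c("KO", "PFAM", "TIGRFAM", "GENUS"),
                       normalized = FALSE) {
  attribute_type <- match.arg(attribute_type)
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) {
    abort("an attribute table needs a `sample` column and at least one attribute column")
  }
  if (names(x)[1] != "sample") {
    abort(paste0(
      "first column must be named `sample` (samples in rows); got `",
      names(x)[1], "`. A transposed table is an error, not auto-detected."
    ))
  }
  x$sample <- as.character(x$sample)
  if (anyDuplicated(x$sample)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(x$sample[duplicated(x$sample)]), collapse = ", ")))
  }
  if (anyDuplicated(names(x))) {
    abort(paste0("duplicate attribute ids: ",
                 paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")))
  }
  for (j in seq(2L, ncol(x))) {
    col <- x[[j]]
    if (!is.numeric(col)) {
      abort(paste0("attribute column `", names(x)[j], "` is not numeric"))
    }
    bad <- which(!is.finite(col) | col < 0)
    if (length(bad)) {
      abort(paste0("negative or non-finite count at sample `",
                   x$sample[bad[1]], "`, attribute `", names(x)[j], "`"))
    }
    if (!normalized) {
      frac <- which(abs(col - round(col)) > 1e-8)
      if (length(frac)) {
        abort(paste0("non-integer count in unnormalized table at sample `",
                     x$sample[frac[1]], "`, attribute `", names(x)[j], "`"))
      }
    }
  }
  structure(x,
            class = c("fp_attr_tbl", class(tibble::tibble())),
            attribute_type = attribute_type,
            normalized = isTRUE(normalized))
}

#' @rdname attr_table
#' @export
attribute_type <- function(x) attr(x, "attribute_type")

#' @rdname attr_table
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Extract the count matrix of an attribute table
#'
#' @param table An [attr_table()].
#' @return A numeric matrix, samples in rows (rownames = sample ids),
#'   attributes in columns.
#' @export
attr_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table)[, -1, drop = FALSE])
  rownames(m) <- table$sample
  m
}

# rebuild an fp_attr_tbl from a matrix, inheriting metadata
attr_table_from_matrix <- function(m, attribute_type, normalized) {
  df <- tibble::as_tibble(m)
  df <- dplyr::bind_cols(tibble::tibble(sample = rownames(m)), df)
  attr_table(df, attribute_type = attribute_type, normalized = normalized)
}

#' Construct an environmental metadata table
#'
#' One row per sample with up to six continuous soil factors — `bulk_density`
#' (kg/dm^3), `cec` (cmol C/kg), `nitrogen` (g/kg), `ph`, `soc` (g/kg),
#' `clay` (%) — and an optional categorical `biome` label. Missing values are
#' allowed; samples missing the factor under study are dropped per-analysis,
#' not globally.
#'
#' @param x A data frame with a `sample` column and a subset of the factor
#'   columns above.
#' @return A tibble of class `fp_env_tbl`.
#' @export
env_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"sample" %in% names(x)) abort("metadata needs a `sample` column")
  x$sample <- as.character(x$sample)
  if (anyDuplicated(x$sample)) abort("duplicate sample ids in metadata")
  known <- intersect(env_factor_names(), names(x))
  if (!length(known)) {
    abort(paste0("no recognised environmental factor columns; expected some of: ",
                 paste(env_factor_names(), collapse = ", ")))
  }
  for (f in known) {
    if (!is.numeric(x[[f]])) abort(paste0("factor `", f, "` is not numeric"))
    v <- x[[f]]
    if (any(!is.finite(v) & !is.na(v))) {
      abort(paste0("non-finite value in factor `", f, "`"))
    }
  }
  if ("ph" %in% names(x) && any(x$ph < 0 | x$ph > 14, na.rm = TRUE)) {
    abort("ph outside [0, 14]")
  }
  if ("clay" %in% names(x) && any(x$clay < 0 | x$clay > 100, na.rm = TRUE)) {
    abort("clay content outside [0, 100] %")
  }
  if ("biome" %in% names(x)) x$biome <- as.character(x$biome)
  structure(x, class = c("fp_env_tbl", class(tibble::tibble())))
}

#' @rdname env_table
#' @export
env_factor_names <- function() {
  c("bulk_density", "cec", "nitrogen", "ph", "soc", "clay")
}

#' Read / write attribute tables
#'
#' Tables are strict tab-separated files: a header row whose first field is
#' `sample`, one row per sample, integer counts (or normalized abundances).
#' Lines starting with `#` are provenance comments and are skipped.
#'
#' @param path File path.
#' @inheritParams attr_table
#' @param normalized Declare the file as containing normalized abundances.
#' @return [read_attribute_table()] returns an [attr_table()];
#'   [write_attribute_table()] returns `path` invisibly.
#' @export
read_attribute_table <- function(path,
                                 attribute_type = c("KO", "PFAM", "TIGRFAM", "GENUS"),
                                 normalized = FALSE) {
  attribute_type <- match.arg(attribute_type)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         sample = readr::col_character(),
                         .default = readr::col_double()
                       ))
  prob <- readr::problems(x)
  if (nrow(prob)) {
    abort(paste0("malformed table `", path, "`: e.g. row ", prob$row[1],
                 ", col ", prob$col[1], ": ", prob$expected[1]))
  }
  attr_table(x, attribute_type = attribute_type, normalized = normalized)
}

#' @rdname read_attribute_table
#' @param table An [attr_table()].
#' @export
write_attribute_table <- function(table, path) {
  header <- sprintf("# soilfp attribute table | attribute_type=%s | normalized=%s",
                    attribute_type(table), is_normalized(table))
  writeLines(header, path)
  readr::write_tsv(tibble::as_tibble(table), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read / write environmental metadata
#'
#' Tab-separated, `sample` column plus factor columns; empty fields encode
#' missing values.
#'
#' @param path File path.
#' @return [read_env_table()] returns an [env_table()].
#' @export
read_env_table <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       na = c("", "NA"))
  env_table(x)
}

#' @rdname read_env_table
#' @param env An [env_table()].
#' @export
write_env_table <- function(env, path) {
  readr::write_tsv(tibble::as_tibble(env), path)
  invisible(path)
}

#' Align an attribute table and metadata on shared samples
#'
#' Restricts both tables to the intersection of their sample ids, in the
#' attribute table's order. Idempotent; an empty intersection is an error.
#'
#' @param table An [attr_table()].
#' @param env An [env_table()].
#' @return A list with elements `table` and `env`, row-aligned.
#' @examples
#' tab <- attr_table(data.frame(sample = c("a", "b", "c"),
#'                              K1 = c(1, 2, 3)), "KO")
#' env <- env_table(data.frame(sample = c("b", "c", "d"),
#'                             ph = c(5, 6, 7)))
#' aligned <- align_samples(tab, env)
#' aligned$table$sample
#' @export
align_samples <- function(table, env) {
  shared <- intersect(table$sample, env$sample)
  if (!length(shared)) abort("no samples shared between attribute table and metadata")
  keep <- table$sample[table$sample %in% shared]
  tab2 <- table[match(keep, table$sample), , drop = FALSE]
  env2 <- env[match(keep, env$sample), , drop = FALSE]
  inform(sprintf("aligned on %d shared sample(s)", length(keep)))
  list(
    table = attr_table(tab2, attribute_type = attribute_type(table),
                       normalized = is_normalized(table)),
    env = env_table(env2)
  )
}

#' Fingerprint reports
#'
#' A fingerprint report is the machine-readable record of one extracted
#' fingerprint: the context (an environmental factor, biome, or cluster id),
#' the direction (`high`/`low` for supervised fingerprints,
#' `abundant`/`variable` for cluster fingerprints), the member attributes with
#' the statistics used to select them, and a full parameter snapshot.
#'
#' @param context Character scalar naming the factor, biome, or cluster.
#' @param direction One of `"high"`, `"low"`, `"abundant"`, `"variable"`.
#' @param members A data frame with column `attribute_id` and optional
#'   `importance`, `slope`, `correlation` columns (may have zero rows).
#' @param parameters A named list, typically an [fp_config()] snapshot.
#' @return An object of class `fp_report`.
#' @export
fp_report <- function(context, direction = c("high", "low", "abundant", "variable"),
                      members, parameters = list()) {
  direction <- match.arg(direction)
  members <- tibble::as_tibble(members)
  if (nrow(members) && !"attribute_id" %in% names(members)) {
    abort("report members need an `attribute_id` column")
  }
  if (!nrow(members) && !"attribute_id" %in% names(members)) {
    members <- tibble::tibble(attribute_id = character())
  }
  structure(
    list(context = as.character(context), direction = direction,
         members = members, parameters = parameters),
    class = "fp_report"
  )
}

#' @rdname fp_report
#' @param reports An `fp_report` or a list of them; several directions of the
#'   same context are stored side by side in one file, keyed by direction.
#' @param path Output JSON path.
#' @export
write_fingerprint_report <- function(reports, path) {
  if (inherits(reports, "fp_report")) reports <- list(reports)
  payload <- purrr::map(reports, function(r) {
    list(context = r$context, direction = r$direction,
         members = r$members, parameters = r$parameters)
  })
  keys <- purrr::map_chr(payload, ~ paste(.x$context, .x$direction, sep = ":"))
  if (anyDuplicated(keys)) abort("duplicate context:direction pair in report set")
  names(payload) <- keys
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname fp_report
#' @export
read_fingerprint_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  purrr::map(unname(raw), function(r) {
    members <- r$members
    if (is.null(members) || (is.data.frame(members) && !nrow(members)) ||
        (!is.data.frame(members) && !length(members))) {
      members <- tibble::tibble(attribute_id = character())
    }
    fp_report(r$context, r$direction, members,
              parameters = if (is.null(r$parameters)) list() else r$parameters)
  })
}
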