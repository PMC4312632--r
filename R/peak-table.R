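#' Construct a peak table
#'
#' A peak table is the package's representation of an LC-MS peak-area export:
#' one row per sample, a `sample_id` column, an optional binary `label`
#' column (1 = minority/excess stratum, 0 = majority/deficiency stratum), and
#' one numeric intensity column per feature. Feature-level metadata
#' (retention time in minutes and m/z) travels in the `"features"` attribute
#' and is retrieved with [peak_features()].
#'
#' @param intensities Numeric samples x features matrix, non-negative.
#' @param features Data frame with columns `feature_id`, `rt_min`, `mz`
#'   (one row per column of `intensities`).
#' @param sample_id Character vector of unique sample identifiers.
#' @param label Optional 0/1 vector of class labels (1 = excess syndrome).
#' @return A tibble of class `peak_tbl`.
#' @export
#' @examples
#' tab <- peak_table(
#'   matrix(1:6, 2, 3),
#'   tibble::tibble(feature_id = c("a", "b", "c"), rt_min = 1:3, mz = 100:102),
#'   sample_id = c("s1", "s2"), label = c(0, 1)
#' )
#' peak_features(tab)
peak_table <- function(intensities, features, sample_id, label = NULL) {
  intensities <- as.matrix(intensities)
  features <- tibble::as_tibble(features)
  stopifnot(all(c("feature_id", "rt_min", "mz") %in% names(features)))
  if (nrow(features) != ncol(intensities)) {
    rlang::abort("`features` must have one row per intensity column")
  }
  if (anyDuplicated(sample_id)) rlang::abort("sample ids must be unique")
  if (anyDuplicated(features$feature_id)) {
    rlang::abort("feature ids must be unique")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    rlang::abort("intensities must be non-negative")
  }
  if (length(sample_id) != nrow(intensities)) {
    rlang::abort("`sample_id` length must equal the number of rows")
  }
  if (!is.null(label)) {
    if (length(label) != nrow(intensities)) {
      rlang::abort("`label` length must equal the number of samples")
    }
    label <- as.integer(label)
    if (any(!is.na(label) & !label %in% c(0L, 1L))) {
      rlang::abort("`label` must be coded 0/1 (1 = excess syndrome)")
    }
  }
  colnames(intensities) <- features$feature_id
  out <- tibble::tibble(sample_id = as.character(sample_id))
  out$label <- if (is.null(label)) NA_integer_ else as.integer(label)
  out <- dplyr::bind_cols(out, tibble::as_tibble(intensities))
  new_peak_tbl(out, features)
}

new_peak_tbl <- function(df, features) {
  structure(df,
    features = tibble::as_tibble(features),
    class = c("peak_tbl", class(tibble::tibble()))
  )
}

#' Feature metadata of a peak table
#'
#' @param table A [peak_table()].
#' @return Tibble with `feature_id`, `rt_min`, `mz`.
#' @export
peak_features <- function(table) {
  ft <- attr(table, "features")
  if (is.null(ft)) rlang::abort("not a peak table (no feature metadata)")
  ft
}

#' Intensity matrix of a peak table
#'
#' @inheritParams peak_features
#' @return Numeric samples x features matrix with sample ids as row names.
#' @export
peak_intensities <- function(table) {
  ft <- peak_features(table)
  x <- as.matrix(table[, ft$feature_id, drop = FALSE])
  rownames(x) <- table$sample_id
  x
}

#' Read / write peak tables
#'
#' The on-disk dialect is the transposed MarkerLynx-style export: a TSV whose
#' first three columns are `feature_id`, `rt_min`, `mz`, followed by one
#' column per sample; labels live in a separate two-column TSV
#' (`sample_id`, `label`).
#'
#' @param path Path of the feature-by-sample TSV.
#' @param labels_path Optional path of the labels TSV.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, labels_path = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("feature_id", "rt_min", "mz") %in% names(raw)))
  features <- raw[, c("feature_id", "rt_min", "mz")]
  x <- t(as.matrix(raw[, setdiff(names(raw), names(features)), drop = FALSE]))
  label <- NULL
  if (!is.null(labels_path)) {
    lab <- readr::read_tsv(labels_path, show_col_types = FALSE)
    label <- lab$label[match(rownames(x), lab$sample_id)]
  }
  peak_table(x, features, sample_id = rownames(x), label = label)
}

#' @rdname read_peak_table
#' @param table A [peak_table()].
#' @export
write_peak_table <- function(table, path, labels_path = NULL) {
  ft <- peak_features(table)
  x <- peak_intensities(table)
  out <- dplyr::bind_cols(ft, tibble::as_tibble(t(x)))
  readr::write_tsv(out, path)
  if (!is.null(labels_path)) {
    readr::write_tsv(
      tibble::tibble(sample_id = table$sample_id, label = table$label),
      labels_path
    )
  }
  invisible(path)
}
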