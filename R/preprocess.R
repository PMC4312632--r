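#' Remove internal-standard ion peaks
#'
#' Drops every feature whose retention time and m/z both fall within the
#' matching window around the spiked internal standard. This is the first
#' preprocessing step and must precede [sum_normalize()], so that the
#' standard's (large, near-constant) peak does not distort the per-sample
#' totals.
#'
#' @param table A [peak_table()].
#' @param is_mz,is_rt Internal-standard m/z and retention time (minutes).
#'   Defaults are the package's simulated L-chlorophenylalanine coordinates.
#' @param mz_tol,rt_tol Positive matching tolerances (m/z units, minutes).
#' @return The peak table without the matched features. A message reports
#'   how many features were removed; a warning is raised when none matched.
#' @export
remove_internal_standard <- function(table, is_mz = IS_MZ, is_rt = IS_RT,
                                     mz_tol = 0.01, rt_tol = 0.1) {
  assert_scalar_number(mz_tol, "mz_tol", lower = 0, strict = TRUE)
  assert_scalar_number(rt_tol, "rt_tol", lower = 0, strict = TRUE)
  ft <- peak_features(table)
  hit <- abs(ft$mz - is_mz) <= mz_tol & abs(ft$rt_min - is_rt) <= rt_tol
  if (!any(hit)) {
    rlang::warn("no feature matched the internal-standard window; table unchanged")
    return(table)
  }
  if (all(hit)) {
    rlang::abort("internal-standard removal would drop every feature")
  }
  rlang::inform(sprintf("removed %d internal-standard feature(s)", sum(hit)))
  keep <- ft$feature_id[!hit]
  new_peak_tbl(
    table[, c("sample_id", "label", keep)],
    ft[!hit, , drop = FALSE]
  )
}

#' Total-sum normalization
#'
#' Divides each sample's intensities by their sum, so every sample's
#' normalized intensities add to one. Applied after internal-standard
#' removal. The operation is idempotent and invariant to per-sample scaling.
#'
#' @param table A [peak_table()].
#' @return The normalized peak table.
#' @export
sum_normalize <- function(table) {
  x <- peak_intensities(table)
  totals <- rowSums(x)
  bad <- which(!is.finite(totals) | totals <= 0)
  if (length(bad)) {
    rlang::abort(sprintf(
      "sample(s) with non-positive total intensity: %s",
      paste(table$sample_id[bad], collapse = ", ")
    ))
  }
  peak_table(x / totals, peak_features(table),
             sample_id = table$sample_id, label = table$label)
}

#' Assemble the model matrix and label vector
#'
#' @param table A [peak_table()] whose samples all carry a 0/1 label.
#' @return A list with `x` (samples x features numeric matrix, dimnames set)
#'   and `y` (integer 0/1 vector, 1 = excess syndrome), in the table's row
#'   and column order.
#' @export
assemble_matrix <- function(table) {
  if (nrow(table) == 0) rlang::abort("empty peak table")
  if (any(is.na(table$label))) {
    rlang::abort(sprintf(
      "missing label for sample(s): %s",
      paste(table$sample_id[is.na(table$label)], collapse = ", ")
    ))
  }
  list(x = peak_intensities(table), y = as.integer(table$label))
}
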