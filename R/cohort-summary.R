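#' Summarize a continuous clinical covariate by group
#'
#' Per-group mean and SD with a two-sided independent-samples t-test
#' (pooled variance by default, matching the classic SPSS primary row;
#' `var_equal = FALSE` switches to Welch).
#'
#' @param values Numeric covariate.
#' @param groups 0/1 group labels (each group needs >= 2 values).
#' @param var_equal Pooled-variance t-test?
#' @return One-row tibble: per-group `n`, `mean`, `sd` (suffixes `0`/`1`),
#'   `statistic`, `p_value`.
#' @export
summarize_continuous <- function(values, groups, var_equal = TRUE) {
  g <- assert_binary_labels(groups, "groups")
  keep <- !is.na(values)
  values <- values[keep]; g <- g[keep]
  if (min(table(g)) < 2) rlang::abort("each group needs at least 2 values")
  tt <- stats::t.test(values[g == 0], values[g == 1], var.equal = var_equal)
  tibble::tibble(
    n0 = sum(g == 0), mean0 = mean(values[g == 0]), sd0 = stats::sd(values[g == 0]),
    n1 = sum(g == 1), mean1 = mean(values[g == 1]), sd1 = stats::sd(values[g == 1]),
    statistic = unname(tt$statistic),
    p_value = tt$p.value
  )
}

#' t-test from printed summary statistics
#'
#' The same independent-samples t-test as [summarize_continuous()], computed
#' from means, SDs and group sizes, so printed cohort tables can be checked
#' without the raw data.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @param var_equal Pooled variance (default) or Welch.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' t_test_from_stats(67.11, 9.49, 57, 71.55, 8.50, 238)
t_test_from_stats <- function(mean1, sd1, n1, mean2, sd2, n2,
                              var_equal = TRUE) {
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  stat <- (mean1 - mean2) / se
  tibble::tibble(statistic = stat, df = df,
                 p_value = 2 * stats::pt(-abs(stat), df))
}

#' Summarize a binary clinical covariate by group
#'
#' Per-group percentage with present/absent counts, formatted
#' `"51.9% (153/142)"` at one decimal, and a Pearson chi-square test without
#' continuity correction (`correct = TRUE` restores Yates).
#'
#' @param flags 0/1 covariate (NAs dropped).
#' @param groups 0/1 group labels.
#' @param correct Apply Yates continuity correction?
#' @return Tibble with one row per group plus the pooled row (`group =
#'   "total"`): `n_present`, `n_absent`, `percent` (unrounded), `formatted`,
#'   and the shared `statistic`, `p_value`, `degenerate` flag (constant
#'   covariate, P undefined).
#' @export
summarize_categorical <- function(flags, groups, correct = FALSE) {
  g <- assert_binary_labels(groups, "groups")
  keep <- !is.na(flags)
  flags <- assert_binary_labels(flags[keep], "flags")
  g <- g[keep]
  if (!length(flags)) rlang::abort("no non-missing observations")
  degenerate <- length(unique(flags)) < 2 || length(unique(g)) < 2
  if (degenerate) {
    stat <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::chisq.test(table(g, flags), correct = correct)
    )
    stat <- unname(ct$statistic); p <- ct$p.value
  }
  one <- function(f) {
    tibble::tibble(
      n_present = sum(f == 1), n_absent = sum(f == 0),
      percent = 100 * sum(f == 1) / length(f)
    )
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(one(flags), group = "total"),
    dplyr::mutate(one(flags[g == 0]), group = "0"),
    dplyr::mutate(one(flags[g == 1]), group = "1")
  )
  out$formatted <- sprintf("%.1f%% (%d/%d)", out$percent,
                           out$n_present, out$n_absent)
  out$statistic <- stat
  out$p_value <- p
  out$degenerate <- degenerate
  out[, c("group", "n_present", "n_absent", "percent", "formatted",
          "statistic", "p_value", "degenerate")]
}

#' Clinical-characteristics summary table
#'
#' Builds the classic baseline table: continuous covariates as mean ± SD per
#' group with t-test P values, binary covariates as percentages with
#' chi-square P values.
#'
#' @param clinical Tibble from [generate_clinical_table()] or of the same
#'   shape (`group` column plus covariates).
#' @param group_col Name of the 0/1 grouping column.
#' @param var_equal,correct Test options, see [summarize_continuous()] and
#'   [summarize_categorical()].
#' @return Tibble with `variable`, `type`, formatted `total`, `group0`,
#'   `group1` columns and `p_value`.
#' @export
cohort_summary <- function(clinical, group_col = "group", var_equal = TRUE,
                           correct = FALSE) {
  g <- clinical[[group_col]]
  if (is.null(g)) rlang::abort(sprintf("no column `%s`", group_col))
  vars <- setdiff(names(clinical), c(group_col, "sample_id"))
  purrr::map_dfr(vars, function(v) {
    val <- clinical[[v]]
    if (all(stats::na.omit(val) %in% c(0, 1))) {
      s <- summarize_categorical(val, g, correct = correct)
      tibble::tibble(
        variable = v, type = "categorical",
        total = s$formatted[s$group == "total"],
        group0 = s$formatted[s$group == "0"],
        group1 = s$formatted[s$group == "1"],
        p_value = s$p_value[1]
      )
    } else {
      s <- summarize_continuous(val, g, var_equal = var_equal)
      fmt <- function(m, sd) sprintf("%.2f ± %.2f", m, sd)
      tibble::tibble(
        variable = v, type = "continuous",
        total = fmt(mean(val, na.rm = TRUE), stats::sd(val, na.rm = TRUE)),
        group0 = fmt(s$mean0, s$sd0),
        group1 = fmt(s$mean1, s$sd1),
        p_value = s$p_value
      )
    }
  })
}
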