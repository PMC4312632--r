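#' Binomial selection-frequency tail probability
#'
#' Probability of a feature being selected at least `x` times in `n`
#' independent GA runs if features were picked at random with probability
#' `m / v`:
#' `P(x) = sum_{i=x}^{n} choose(n, i) (m/v)^i (1 - m/v)^(n-i)`,
#' computed through the numerically stable binomial survival function.
#'
#' @param x Observed selection count(s), `0 <= x <= n` (vectorized).
#' @param n Number of GA runs.
#' @param m Mean number of features selected per run, rounded to an integer.
#' @param v Total number of features.
#' @return Upper-tail probability in \[0, 1\], exact at the boundaries
#'   (`x = 0` gives 1, `x = n` gives `(m/v)^n`).
#' @export
#' @examples
#' binomial_selection_pvalue(14, n = 50, m = 13, v = 135)
binomial_selection_pvalue <- function(x, n, m, v) {
  n <- assert_count(n, "n")
  m <- assert_count(m, "m")
  v <- assert_count(v, "v")
  if (m > v) rlang::abort("`m` cannot exceed `v`")
  if (any(x < 0 | x > n)) rlang::abort("`x` must satisfy 0 <= x <= n")
  stats::pbinom(x - 1, size = n, prob = m / v, lower.tail = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midrank (tie-aware) rank-sum statistic. For combined sample sizes up to
#' `exact_limit` the P value is exact: the full permutation distribution of
#' the rank sum over all group assignments, with the two-sided region
#' defined by distance from the null mean (so ties in the data are handled
#' exactly, unlike the exact path of `stats::wilcox.test`). Larger samples
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param values_class1,values_class0 Numeric observations of the two groups
#'   (both nonempty).
#' @param exact_limit Largest combined size for the enumeration path.
#' @return Two-sided P value.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3)) # 2/20 orderings as extreme
wilcoxon_rank_sum <- function(values_class1, values_class0,
                              exact_limit = 12) {
  a <- as.numeric(values_class1)
  b <- as.numeric(values_class0)
  if (!length(a) || !length(b)) rlang::abort("both groups must be nonempty")
  n1 <- length(a)
  nn <- n1 + length(b)
  if (nn <= exact_limit) {
    r <- rank(c(a, b))
    w_obs <- sum(r[seq_len(n1)])
    e_w <- n1 * (nn + 1) / 2
    sets <- utils::combn(nn, n1)
    w_all <- colSums(matrix(r[sets], nrow = n1))
    return(mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9))
  }
  stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
}

#' Call differential features by the dual criterion
#'
#' A feature is differential when it passes both the multivariate GA
#' selection-frequency test (`p_ga < alpha_ga`) and the univariate Wilcoxon
#' rank-sum test (`p_wilcoxon < alpha_wx`). Direction is the sign of the
#' minority-class (excess) median minus the majority-class (deficiency)
#' median, so +1 means higher in the excess stratum.
#'
#' @param counts A `selection_counts` tibble from [ga_select()].
#' @param x Feature matrix sharing the counts' feature order.
#' @param y 0/1 labels.
#' @param alpha_ga GA selection-frequency significance threshold.
#' @param alpha_wx Wilcoxon significance threshold.
#' @return Tibble with one row per feature: `feature_id`, `count`, `n_runs`,
#'   `p_ga`, `p_wilcoxon`, `direction`, `passes`.
#' @export
call_differentials <- function(counts, x, y, alpha_ga = 0.001,
                               alpha_wx = 0.05) {
  x <- as.matrix(x)
  y <- assert_binary_labels(y)
  n <- attr(counts, "n_runs")
  v <- attr(counts, "n_features")
  m <- attr(counts, "m")
  if (is.null(n) || is.null(v) || is.null(m)) {
    rlang::abort("`counts` must come from ga_select()")
  }
  if (ncol(x) != v || nrow(counts) != v) {
    rlang::abort("`x` and `counts` must share feature indexing")
  }
  m_eff <- max(m, 1L) # m = 0 only when every tally is 0, where P = 1 anyway
  p_ga <- binomial_selection_pvalue(counts$count, n = n, m = m_eff, v = v)
  p_wx <- vapply(seq_len(v), function(j) {
    wilcoxon_rank_sum(x[y == 1L, j], x[y == 0L, j])
  }, numeric(1))
  direction <- sign(apply(x[y == 1L, , drop = FALSE], 2, stats::median) -
                      apply(x[y == 0L, , drop = FALSE], 2, stats::median))
  tibble::tibble(
    feature_id = counts$feature_id,
    count = counts$count,
    n_runs = n,
    p_ga = p_ga,
    p_wilcoxon = p_wx,
    direction = as.integer(direction),
    passes = p_ga < alpha_ga & p_wx < alpha_wx
  )
}
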