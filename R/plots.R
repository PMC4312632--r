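#' Score plot of a kernel-OPLS model
#'
#' First predictive score against the first Y-orthogonal score (or sample
#' index when `ao = 0`), coloured by class — the classic OPLS-DA view of the
#' class separation.
#'
#' @param object A `kopls` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kopls <- function(object, ...) {
  df <- tidy(object)
  df$label <- factor(df$label, c(0, 1), c("deficiency (0)", "excess (1)"))
  if (object$core$ao > 0) {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$t_p, .data$t_o1,
                                          colour = .data$label)) +
      ggplot2::labs(y = "first Y-orthogonal score (t_o)")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$t_p, .data$sample,
                                          colour = .data$label)) +
      ggplot2::labs(y = "sample")
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "predictive score (t_p)", colour = NULL,
                  title = "Kernel-OPLS score plot") +
    ggplot2::theme_minimal()
}

#' ACCV surface of a kernel-width / component grid search
#'
#' @param object A `kopls_tune` result.
#' @param ... Unused.
#' @return A ggplot tile map of ACCV over (sigma, Ao).
#' @export
autoplot.kopls_tune <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(factor(.data$sigma), factor(.data$ao),
                               fill = .data$accv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "ACCV") +
    ggplot2::labs(x = expression(sigma), y = "Y-orthogonal components (Ao)",
                  title = "Cross-validated classification accuracy") +
    ggplot2::theme_minimal()
}

#' Selection-count profile over GA runs
#'
#' Bar chart of how often each feature entered the best mask across the
#' independent GA runs, with the critical count at which the binomial
#' selection-frequency test drops below `alpha` drawn as a horizontal line.
#'
#' @param object A `selection_counts` tibble from [ga_select()].
#' @param alpha Significance threshold for the critical-count line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_counts <- function(object, alpha = 0.001, ...) {
  n <- attr(object, "n_runs")
  v <- attr(object, "n_features")
  m <- max(attr(object, "m"), 1L)
  below <- which(binomial_selection_pvalue(0:n, n, m, v) < alpha)
  crit <- if (length(below)) min(below) - 1L else n + 1L
  df <- tibble::tibble(
    index = seq_len(nrow(object)),
    feature_id = object$feature_id,
    count = object$count
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$count)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = crit - 0.5, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "feature index", y = sprintf("times selected / %d runs", n),
                  title = "GA selection frequencies",
                  subtitle = sprintf("dashed line: binomial P < %g", alpha)) +
    ggplot2::theme_minimal()
}

#' Differential-call overview of a stratification result
#'
#' Mirrors the univariate panel of the dual criterion: per-feature
#' `1 - P` from the Wilcoxon rank-sum test, with called features
#' highlighted.
#'
#' @param object A `stratification_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stratification_result <- function(object, ...) {
  df <- object$calls
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$index, 1 - .data$p_wilcoxon,
                                   fill = .data$passes)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = 1 - object$config$alpha_wx,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               name = "dual criterion") +
    ggplot2::labs(x = "feature index", y = "1 - P (Wilcoxon)",
                  title = "Differential-metabolite calls") +
    ggplot2::theme_minimal()
}
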