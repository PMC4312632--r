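#' Confusion-matrix classification metrics
#'
#' Class 1 (excess syndrome, the minority class) is the positive class.
#' Balanced accuracy is the arithmetic mean of sensitivity and specificity;
#' its complement is the balanced prediction error minimized by the GA
#' fitness (see [balanced_error()], a single shared definition).
#'
#' @param y_true,y_pred 0/1 vectors of equal length; `y_true` must contain
#'   both classes.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `total_accuracy`, `balanced_accuracy`.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion_metrics <- function(y_true, y_pred) {
  y_true <- assert_binary_labels(y_true, "y_true")
  y_pred <- assert_binary_labels(y_pred, "y_pred")
  if (length(y_true) != length(y_pred)) {
    rlang::abort("`y_true` and `y_pred` must have equal length")
  }
  if (length(unique(y_true)) < 2) {
    rlang::abort("`y_true` must contain both classes")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec,
    total_accuracy = (tp + tn) / length(y_true),
    balanced_accuracy = (sens + spec) / 2
  )
}

#' Balanced prediction error
#'
#' `1 - (sensitivity + specificity) / 2`; the GA fitness.
#'
#' @inheritParams confusion_metrics
#' @return A single number in \[0, 1\].
#' @export
balanced_error <- function(y_true, y_pred) {
  1 - confusion_metrics(y_true, y_pred)$balanced_accuracy
}

#' Area under the ROC curve
#'
#' Mann-Whitney AUC (ties count one half), computed through \pkg{pROC}.
#'
#' @param y_true 0/1 labels containing both classes.
#' @param scores Continuous classifier scores (larger = more class 1).
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(y_true, scores) {
  y_true <- assert_binary_labels(y_true, "y_true")
  if (length(unique(y_true)) < 2) {
    rlang::abort("`y_true` must contain both classes")
  }
  as.numeric(pROC::auc(pROC::roc(
    response = y_true, predictor = as.numeric(scores),
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

#' DeLong confidence interval for the AUC
#'
#' @inheritParams auc_mw
#' @param level Confidence level.
#' @return One-row tibble `auc`, `ci_low`, `ci_high`, `level`, truncated to
#'   \[0, 1\]. If the variance estimate is unavailable (degenerate or tiny
#'   samples) the interval widens to \[0, 1\] with a warning.
#' @export
auc_ci <- function(y_true, scores, level = 0.95) {
  a <- auc_mw(y_true, scores)
  ci <- tryCatch(
    {
      r <- pROC::roc(response = assert_binary_labels(y_true),
                     predictor = as.numeric(scores),
                     levels = c(0, 1), direction = "<", quiet = TRUE)
      as.numeric(pROC::ci.auc(r, conf.level = level, method = "delong"))
    },
    error = function(e) NULL
  )
  if (is.null(ci) || anyNA(ci)) {
    rlang::warn("AUC variance estimate unavailable; widening interval to [0, 1]")
    ci <- c(0, a, 1)
  }
  tibble::tibble(
    auc = a,
    ci_low = max(0, min(ci[1], a)),
    ci_high = min(1, max(ci[3], a)),
    level = level
  )
}
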