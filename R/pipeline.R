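#' Pipeline configuration
#'
#' Bundles the settings of every stage of [run_stratification()]. Defaults
#' are the study conditions: internal-standard removal then total-sum
#' normalization; SMOTE to full balance; GA selection with the reported GA
#' settings; a kernel-width grid of 0.5-5 and 0-5 orthogonal components
#' tuned by 10-fold ACCV; dual-criterion calling at `alpha_ga = 0.001`,
#' `alpha_wx = 0.05`.
#'
#' @param is_mz,is_rt,mz_tol,rt_tol Internal-standard window (set `is_mz =
#'   NULL` to skip removal).
#' @param smote_n SMOTE neighbour parameter used when `optimize_smote` is
#'   `FALSE`.
#' @param optimize_smote Optimize the neighbour parameter first?
#' @param smote_n_grid,smote_n_repeats Grid and repeats for the optimizer.
#' @param target_ratio SMOTE target minority:majority ratio.
#' @param ga A [ga_config()].
#' @param ga_sigma,ga_ao Kernel-OPLS settings used inside the GA fitness
#'   (`ga_sigma = NULL` is the median-distance heuristic).
#' @param ga_fitness GA fitness protocol, `"test"` or `"cv"` (see
#'   [ga_select()]).
#' @param ga_cv_folds Cross-validation folds when `ga_fitness = "cv"`.
#' @param sigma_grid,ao_grid,n_folds Final-model ACCV grid search.
#' @param alpha_ga,alpha_wx Dual-criterion thresholds.
#' @param strict_holdout Score GA fitness on the untouched half split.
#' @param holdout_report Also evaluate the final model on a held-out half.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(is_mz = IS_MZ, is_rt = IS_RT, mz_tol = 0.01,
                            rt_tol = 0.1, smote_n = 5,
                            optimize_smote = FALSE, smote_n_grid = 1:10,
                            smote_n_repeats = 10, target_ratio = 1,
                            ga = ga_config(),
                            ga_sigma = NULL, ga_ao = 1,
                            ga_fitness = "test", ga_cv_folds = 5,
                            sigma_grid = c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5),
                            ao_grid = 0:5, n_folds = 10,
                            alpha_ga = 0.001, alpha_wx = 0.05,
                            strict_holdout = FALSE, holdout_report = TRUE,
                            seed = 1) {
  structure(
    list(is_mz = is_mz, is_rt = is_rt, mz_tol = mz_tol, rt_tol = rt_tol,
         smote_n = smote_n, optimize_smote = optimize_smote,
         smote_n_grid = smote_n_grid, smote_n_repeats = smote_n_repeats,
         target_ratio = target_ratio, ga = ga, ga_sigma = ga_sigma,
         ga_ao = ga_ao, ga_fitness = ga_fitness, ga_cv_folds = ga_cv_folds,
         sigma_grid = sigma_grid, ao_grid = ao_grid,
         n_folds = n_folds, alpha_ga = alpha_ga, alpha_wx = alpha_wx,
         strict_holdout = strict_holdout, holdout_report = holdout_report,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full stratification pipeline
#'
#' Stage order is fixed: (1) preprocess — internal-standard removal then
#' total-sum normalization; (2) SMOTE neighbour choice (fixed or optimized);
#' (3) repeated GA-KOPLS runs producing selection counts; (4) dual-criterion
#' differential calling; (5) final kernel-OPLS model on the GA-selected
#' features — tuned by ACCV grid search on the SMOTE-balanced cohort and
#' evaluated both on the original cohort (resubstitution, the study
#' protocol, optimistic) and on a held-out half (honest), each labelled in
#' the report. Deterministic given the master seed.
#'
#' @param table A labelled [peak_table()].
#' @param config A [pipeline_config()].
#' @return Object of class `stratification_result`: `report` (one row per
#'   evaluation mode with sigma, ao, accv, r2x, r2y, q2y, auc + CI,
#'   sensitivity, specificity, total and balanced accuracy), `calls`
#'   (differential-call tibble), `counts`, `tune`, `model`,
#'   `selected_features`, `smote_n`, `config`.
#' @export
run_stratification <- function(table, config = pipeline_config()) {
  # stage 1: preprocess
  if (!is.null(config$is_mz)) {
    table <- remove_internal_standard(table, config$is_mz, config$is_rt,
                                      config$mz_tol, config$rt_tol)
  }
  table <- sum_normalize(table)
  xy <- assemble_matrix(table)
  x <- xy$x
  y <- xy$y

  # stage 2: SMOTE neighbour parameter
  smote_opt <- NULL
  smote_n <- config$smote_n
  if (isTRUE(config$optimize_smote)) {
    smote_opt <- optimize_smote_n(
      x, y, n_grid = config$smote_n_grid, n_repeats = config$smote_n_repeats,
      ga = config$ga, sigma = config$ga_sigma, ao = config$ga_ao,
      target_ratio = config$target_ratio,
      strict_holdout = config$strict_holdout,
      seed = derive_seed(config$seed, 2L)
    )
    smote_n <- smote_opt$best_n
  }

  # stage 3: repeated GA selection
  counts <- ga_select(
    x, y, config = ga_config_update(config$ga,
                                    seed = derive_seed(config$seed, 3L)),
    n_neighbors = smote_n, target_ratio = config$target_ratio,
    sigma = config$ga_sigma, ao = config$ga_ao,
    fitness = config$ga_fitness, cv_folds = config$ga_cv_folds,
    strict_holdout = config$strict_holdout
  )

  # stage 4: dual-criterion calls
  calls <- call_differentials(counts, x, y,
                              alpha_ga = config$alpha_ga,
                              alpha_wx = config$alpha_wx)

  # stage 5: final model on GA-selected features
  selected <- calls$feature_id[calls$p_ga < config$alpha_ga]
  if (!length(selected)) {
    rlang::warn("no feature passed the GA criterion; using all features")
    selected <- calls$feature_id
  }
  xs <- x[, selected, drop = FALSE]
  eval_one <- function(x_train, y_train, x_eval, y_eval, label, stage) {
    sseed <- derive_seed(config$seed, stage)
    bal <- smote_balance(x_train, y_train, n_neighbors = smote_n,
                         target_ratio = config$target_ratio, seed = sseed)
    n_folds <- min(config$n_folds, min(base::table(bal$y)))
    tune <- kopls_tune(bal$x, bal$y, sigma_grid = config$sigma_grid,
                       ao_grid = config$ao_grid, n_folds = n_folds,
                       seed = sseed + 1L)
    model <- kopls_fit(bal$x, bal$y, sigma = tune$best_sigma,
                       ao = tune$best_ao)
    stats <- kopls_fit_stats(bal$x, bal$y, sigma = tune$best_sigma,
                             ao = tune$best_ao, n_folds = n_folds,
                             seed = sseed + 2L)
    scores <- predict(model, x_eval)
    cm <- confusion_metrics(y_eval, as.integer(scores >= 0.5))
    ci <- auc_ci(y_eval, scores)
    list(
      model = model, tune = tune,
      report = tibble::tibble(
        evaluation = label, sigma = tune$best_sigma, ao = tune$best_ao,
        accv = tune$best_accv, r2x = stats$r2x, r2y = stats$r2y,
        q2y = stats$q2y, auc = ci$auc, ci_low = ci$ci_low,
        ci_high = ci$ci_high, sensitivity = cm$sensitivity,
        specificity = cm$specificity, total_accuracy = cm$total_accuracy,
        balanced_accuracy = cm$balanced_accuracy
      )
    )
  }
  resub <- eval_one(xs, y, xs, y, "resubstitution", 5L)
  report <- resub$report
  if (isTRUE(config$holdout_report)) {
    tr <- stratified_half_split(y, seed = derive_seed(config$seed, 6L))
    te <- setdiff(seq_along(y), tr)
    hold <- eval_one(xs[tr, , drop = FALSE], y[tr],
                     xs[te, , drop = FALSE], y[te], "holdout", 7L)
    report <- dplyr::bind_rows(report, hold$report)
  }
  structure(
    list(report = report, calls = calls, counts = counts,
         tune = resub$tune, model = resub$model,
         selected_features = selected, smote_n = smote_n,
         smote_opt = smote_opt, table = table, config = config),
    class = "stratification_result"
  )
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf(
    "Stratification result: %d differential call(s) of %d features\n",
    sum(x$calls$passes), nrow(x$calls)
  ))
  cat(sprintf("  SMOTE n = %d; final model sigma = %.4g, Ao = %d\n",
              x$smote_n, x$report$sigma[1], x$report$ao[1]))
  print(x$report[, c("evaluation", "accv", "q2y", "auc", "sensitivity",
                     "specificity", "balanced_accuracy")])
  invisible(x)
}

#' Differential calls of a stratification result
#'
#' @param x A `stratification_result`.
#' @param ... Unused.
#' @return The differential-call tibble.
#' @export
tidy.stratification_result <- function(x, ...) x$calls

#' Model report of a stratification result
#'
#' @param x A `stratification_result`.
#' @param ... Unused.
#' @return The per-evaluation-mode model report tibble.
#' @export
glance.stratification_result <- function(x, ...) x$report

#' Subgroup robustness re-analysis
#'
#' Splits the cohort at a covariate cutoff (`low`: covariate <= cutoff,
#' `high`: covariate > cutoff), refits the final kernel-OPLS model with the
#' same kernel width and component count inside each subgroup containing
#' both classes, and tests every called feature between the two subgroups
#' with a Mann-Whitney (Wilcoxon rank-sum) test — covariate-independent
#' signals should give P > 0.05 throughout.
#'
#' @param result A [run_stratification()] result.
#' @param covariate Numeric vector aligned with the cohort's samples.
#' @param cutoff Split point.
#' @return List with `sizes` (named subgroup sizes), `reports` (per-subgroup
#'   model report), and `feature_tests` (`feature_id`, `p_value` between
#'   subgroups).
#' @export
subgroup_robustness <- function(result, covariate, cutoff) {
  ptab <- result$table
  if (length(covariate) != nrow(ptab)) {
    rlang::abort("`covariate` must align with the cohort samples")
  }
  xy <- assemble_matrix(ptab)
  xs <- xy$x[, result$selected_features, drop = FALSE]
  y <- xy$y
  groups <- list(low = covariate <= cutoff, high = covariate > cutoff)
  groups <- groups[vapply(groups, any, logical(1))]
  if (length(groups) < 2) {
    rlang::warn("one subgroup is empty; refitting on the full cohort only")
  }
  sigma <- result$report$sigma[1]
  ao <- result$report$ao[1]
  reports <- purrr::imap_dfr(groups, function(keep, nm) {
    ys <- y[keep]
    if (length(unique(ys)) < 2) {
      rlang::abort(sprintf("subgroup '%s' lacks one of the classes", nm))
    }
    bal <- smote_balance(xs[keep, , drop = FALSE], ys,
                         n_neighbors = min(result$smote_n,
                                           min(base::table(ys)) - 1L),
                         target_ratio = result$config$target_ratio,
                         seed = derive_seed(result$config$seed, 8L))
    model <- kopls_fit(bal$x, bal$y, sigma = sigma, ao = ao)
    scores <- predict(model, xs[keep, , drop = FALSE])
    cm <- confusion_metrics(ys, as.integer(scores >= 0.5))
    ci <- auc_ci(ys, scores)
    tibble::tibble(
      subgroup = nm, n = sum(keep), sigma = sigma, ao = ao,
      auc = ci$auc, sensitivity = cm$sensitivity,
      specificity = cm$specificity,
      balanced_accuracy = cm$balanced_accuracy
    )
  })
  called <- result$calls$feature_id[result$calls$passes]
  feature_tests <- tibble::tibble(
    feature_id = called,
    p_value = vapply(called, function(f) {
      if (length(groups) < 2) return(NA_real_)
      wilcoxon_rank_sum(xy$x[groups$high, f], xy$x[groups$low, f])
    }, numeric(1))
  )
  list(
    sizes = vapply(groups, sum, integer(1)),
    reports = reports,
    feature_tests = feature_tests
  )
}
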