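#' SMOTE synthetic minority samples
#'
#' Each synthetic point is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`,
#' where `x` is a minority sample drawn uniformly with replacement and
#' `x_nn` one of its `n_neighbors` nearest minority neighbours (Euclidean
#' distance, self excluded). Synthetic points therefore lie on segments
#' between minority samples and never leave the minority convex hull; the
#' originals are untouched.
#'
#' @param x_minority Numeric matrix of minority-class samples.
#' @param n_synthetic Number of synthetic points to generate.
#' @param n_neighbors Nearest-neighbour parameter ("n").
#' @param seed RNG seed.
#' @return `n_synthetic x ncol(x_minority)` matrix with attributes
#'   `parent`, `neighbor` (row indices into `x_minority`) and `u` (the
#'   interpolation draws), so the convex-combination geometry is checkable.
#' @export
smote_oversample <- function(x_minority, n_synthetic, n_neighbors = 5,
                             seed = NULL) {
  x <- as.matrix(x_minority)
  n <- nrow(x)
  n_neighbors <- assert_count(n_neighbors, "n_neighbors")
  n_synthetic <- assert_count(n_synthetic, "n_synthetic", lower = 0L)
  if (n <= n_neighbors) {
    rlang::abort("minority count must exceed `n_neighbors`")
  }
  if (n_synthetic == 0L) {
    out <- x[0, , drop = FALSE]
    attr(out, "parent") <- integer(0)
    attr(out, "neighbor") <- integer(0)
    attr(out, "u") <- numeric(0)
    return(out)
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  # n x n_neighbors matrix of nearest-neighbour indices
  ord <- apply(d, 1, function(r) order(r)[seq_len(n_neighbors)])
  nn <- if (n_neighbors == 1L) matrix(ord, ncol = 1L) else t(ord)
  with_seed_if(seed, {
    parent <- sample.int(n, n_synthetic, replace = TRUE)
    pick <- sample.int(n_neighbors, n_synthetic, replace = TRUE)
    u <- stats::runif(n_synthetic)
  })
  neighbor <- nn[cbind(parent, pick)]
  synth <- x[parent, , drop = FALSE] +
    u * (x[neighbor, , drop = FALSE] - x[parent, , drop = FALSE])
  rownames(synth) <- sprintf("synth%04d", seq_len(n_synthetic))
  attr(synth, "parent") <- parent
  attr(synth, "neighbor") <- neighbor
  attr(synth, "u") <- u
  synth
}

#' Rebalance a two-class data set with SMOTE
#'
#' Oversamples the minority class until `minority : majority =
#' target_ratio`. Original rows come first, unchanged; synthetic rows are
#' appended with the minority label.
#'
#' @param x Numeric samples x features matrix.
#' @param y 0/1 labels.
#' @param n_neighbors SMOTE nearest-neighbour parameter.
#' @param target_ratio Desired minority:majority ratio in (0, 1].
#' @param seed RNG seed.
#' @return List with `x`, `y` (augmented), and `synthetic` (logical mask of
#'   appended rows).
#' @export
smote_balance <- function(x, y, n_neighbors = 5, target_ratio = 1,
                          seed = NULL) {
  x <- as.matrix(x)
  y <- assert_binary_labels(y)
  assert_scalar_number(target_ratio, "target_ratio", lower = 0, strict = TRUE)
  if (target_ratio > 1) rlang::abort("`target_ratio` must be in (0, 1]")
  counts <- table(factor(y, levels = c(0, 1)))
  minority <- as.integer(names(counts)[which.min(counts)])
  n_min <- min(counts)
  n_maj <- max(counts)
  n_new <- max(0L, as.integer(round(target_ratio * n_maj) - n_min))
  if (n_new == 0L) {
    return(list(x = x, y = y, synthetic = rep(FALSE, length(y))))
  }
  synth <- smote_oversample(x[y == minority, , drop = FALSE],
                            n_synthetic = n_new,
                            n_neighbors = n_neighbors, seed = seed)
  list(
    x = rbind(x, synth),
    y = c(y, rep(minority, n_new)),
    synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_new))
  )
}

#' Optimize the SMOTE nearest-neighbour parameter
#'
#' For each candidate `n`: draw a stratified 50% training split, rebalance
#' the training half by SMOTE with that `n`, run one GA-KOPLS selection, and
#' record the best balanced prediction error scored on the evaluation set.
#' Following the study protocol the evaluation set is the *full original*
#' cohort (which overlaps the training half and is therefore optimistic);
#' `strict_holdout = TRUE` scores on the untouched half instead. The
#' procedure repeats `n_repeats` times per candidate with fresh splits; the
#' best `n` minimizes the mean error, ties going to the smaller `n`.
#'
#' @param x,y Feature matrix and 0/1 labels.
#' @param n_grid Candidate neighbour counts.
#' @param n_repeats Split repetitions per candidate.
#' @param ga A [ga_config()] for the inner GA runs.
#' @param sigma,ao Kernel-OPLS settings for the fitness classifier.
#' @param target_ratio SMOTE target minority:majority ratio.
#' @param strict_holdout Score on the held-out half instead of the full set.
#' @param seed Master seed.
#' @return List of class `smote_opt` with `best_n` and the per-candidate
#'   `errors` tibble (`n`, `mean_error`, `sd_error`).
#' @export
optimize_smote_n <- function(x, y, n_grid = 1:10, n_repeats = 10,
                             ga = ga_config(), sigma = NULL, ao = 1,
                             target_ratio = 1, strict_holdout = FALSE,
                             seed = 1) {
  if (!length(n_grid)) rlang::abort("`n_grid` must be nonempty")
  x <- as.matrix(x)
  y <- assert_binary_labels(y)
  half_minority <- floor(min(table(y)) / 2)
  if (any(n_grid >= half_minority)) {
    rlang::abort("every candidate `n` must be below the half-split minority count")
  }
  res <- purrr::map_dfr(sort(unique(n_grid)), function(nn) {
    errs <- vapply(seq_len(n_repeats), function(r) {
      sseed <- derive_seed(seed, nn, r)
      tr <- stratified_half_split(y, seed = sseed)
      bal <- smote_balance(x[tr, , drop = FALSE], y[tr],
                           n_neighbors = nn, target_ratio = target_ratio,
                           seed = sseed + 1L)
      te <- if (strict_holdout) setdiff(seq_along(y), tr) else seq_along(y)
      fitness <- make_kopls_fitness(bal$x, bal$y,
                                    x[te, , drop = FALSE], y[te],
                                    sigma = sigma, ao = ao)
      run <- run_ga(fitness, ncol(x),
                    ga_config_update(ga, seed = sseed + 2L))
      run$best_fitness
    }, numeric(1))
    tibble::tibble(n = nn, mean_error = mean(errs), sd_error = stats::sd(errs))
  })
  best <- res$n[order(res$mean_error, res$n)][1]
  structure(list(best_n = best, errors = res), class = "smote_opt")
}
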