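#' Genetic-algorithm configuration
#'
#' Defaults follow the study's reported GA settings: population 30, 150
#' generations, initial per-gene selection ratio 0.1, single-point crossover
#' probability 0.7, plus simple-GA choices where the study is silent:
#' windowed fitness-proportional selection, elitism of one, bitwise
#' mutation at 0.002 per bit (low enough that mask sizes stay near the
#' initial `0.1 * v` instead of drifting toward `v/2`; see the methods
#' vignette), and 50 independent runs for the selection tallies.
#'
#' @param population_size Chromosomes per generation (>= 2).
#' @param n_generations Number of generations.
#' @param init_selection_ratio Probability that a gene starts switched on.
#' @param crossover_prob Single-point crossover probability per pair.
#' @param mutation_prob Per-bit mutation probability.
#' @param n_runs Independent GA runs for [ga_select()].
#' @param seed RNG seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 30, n_generations = 150,
                      init_selection_ratio = 0.1, crossover_prob = 0.7,
                      mutation_prob = 0.002, n_runs = 50, seed = 1) {
  population_size <- assert_count(population_size, "population_size", 2L)
  n_generations <- assert_count(n_generations, "n_generations")
  n_runs <- assert_count(n_runs, "n_runs")
  for (p in c("init_selection_ratio", "crossover_prob", "mutation_prob")) {
    val <- get(p)
    assert_scalar_number(val, p, lower = 0)
    if (val > 1) rlang::abort(sprintf("`%s` must be in [0, 1]", p))
  }
  structure(
    list(population_size = population_size, n_generations = n_generations,
         init_selection_ratio = init_selection_ratio,
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         n_runs = n_runs, seed = as.integer(seed)),
    class = "ga_config"
  )
}

ga_config_update <- function(config, ...) {
  dots <- list(...)
  config[names(dots)] <- dots
  config
}

# Fitness closure: balanced error of a kernel-OPLS classifier trained on
# (x_train, y_train) restricted to the masked features and scored on
# (x_test, y_test). Empty masks score the worst possible error, 1. The
# default engine is the compiled path; engine = "r" goes through
# kopls_fit()/predict() and exists as the reference the compiled path must
# reproduce (asserted in the tests).
make_kopls_fitness <- function(x_train, y_train, x_test, y_test,
                               sigma = NULL, ao = 1,
                               engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  y_train <- as.numeric(y_train)
  y_test <- as.numeric(y_test)
  force(sigma); force(ao)
  if (engine == "cpp") {
    sg <- if (is.null(sigma)) -1 else sigma
    return(function(mask) {
      mask <- as.logical(mask)
      if (!any(mask)) return(1)
      .kopls_mask_error_cpp(x_train, y_train, x_test, y_test,
                            which(mask) - 1L, sg, as.integer(ao))
    })
  }
  function(mask) {
    mask <- as.logical(mask)
    if (!any(mask)) return(1)
    fit <- tryCatch(
      kopls_fit(x_train[, mask, drop = FALSE], y_train,
                sigma = sigma, ao = ao),
      error = function(e) NULL
    )
    if (is.null(fit)) return(1)
    yhat <- predict(fit, x_test[, mask, drop = FALSE], type = "class")
    balanced_error(y_test, yhat)
  }
}

# CV fitness closure: pooled k-fold cross-validated balanced error of the
# masked kernel-OPLS classifier within (x_train, y_train). The fold
# assignment is drawn once (stratified, seeded) and shared by every mask;
# the sigma heuristic, when active, uses the median masked distance over
# the whole training set so folds see a common kernel. engine = "r" is the
# reference implementation the compiled path must reproduce.
make_kopls_cv_fitness <- function(x_train, y_train, n_folds = 5, seed = 1,
                                  sigma = NULL, ao = 1,
                                  engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  x_train <- as.matrix(x_train)
  y_train <- as.numeric(y_train)
  folds <- make_stratified_folds(y_train, n_folds, seed = seed)
  force(sigma); force(ao)
  if (engine == "cpp") {
    sg <- if (is.null(sigma)) -1 else sigma
    return(function(mask) {
      mask <- as.logical(mask)
      if (!any(mask)) return(1)
      .kopls_cv_mask_error_cpp(x_train, y_train, as.integer(folds),
                               which(mask) - 1L, sg, as.integer(ao))
    })
  }
  function(mask) {
    mask <- as.logical(mask)
    if (!any(mask)) return(1)
    xm <- x_train[, mask, drop = FALSE]
    sg <- if (is.null(sigma)) median_sigma(xm, max_n = nrow(xm)) else sigma
    tp <- fn <- tn <- fp <- 0L
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      fit <- tryCatch(
        kopls_fit(xm[tr, , drop = FALSE], y_train[tr], sigma = sg, ao = ao),
        error = function(e) NULL
      )
      if (is.null(fit)) return(1)
      yhat <- predict(fit, xm[!tr, , drop = FALSE], type = "class")
      yte <- y_train[!tr]
      tp <- tp + sum(yte == 1 & yhat == 1)
      fn <- fn + sum(yte == 1 & yhat == 0)
      tn <- tn + sum(yte == 0 & yhat == 0)
      fp <- fp + sum(yte == 0 & yhat == 1)
    }
    if (tp + fn == 0 || tn + fp == 0) return(1)
    1 - 0.5 * (tp / (tp + fn) + tn / (tn + fp))
  }
}

#' Balanced-error fitness of a feature mask
#'
#' Evaluates the GA objective for one chromosome: the kernel-OPLS classifier
#' restricted to the masked features, trained on the (optionally
#' SMOTE-rebalanced) training samples and scored by balanced prediction
#' error. With `test_idx` supplied the score comes from predicting those
#' samples; otherwise it is the pooled balanced error of stratified
#' `n_folds` cross-validation within the training set.
#'
#' @param mask Logical (or 0/1) feature mask. An empty mask returns the
#'   worst fitness, 1, rather than an error.
#' @param x,y Full feature matrix and 0/1 labels.
#' @param train_idx Row indices used for training.
#' @param test_idx Optional row indices scored against the trained model.
#' @param n_neighbors SMOTE neighbour parameter; `NULL` disables
#'   rebalancing.
#' @param target_ratio SMOTE target ratio.
#' @param sigma,ao Kernel-OPLS settings.
#' @param n_folds CV folds when `test_idx` is absent.
#' @param seed RNG seed (SMOTE draws and fold assignment).
#' @return Balanced prediction error in \[0, 1\].
#' @export
evaluate_fitness <- function(mask, x, y, train_idx = seq_along(y),
                             test_idx = NULL, n_neighbors = 5,
                             target_ratio = 1, sigma = NULL, ao = 1,
                             n_folds = 5, seed = 1) {
  mask <- as.logical(mask)
  if (!any(mask)) return(1)
  x <- as.matrix(x)
  y <- assert_binary_labels(y)
  xtr <- x[train_idx, mask, drop = FALSE]
  ytr <- y[train_idx]
  if (!is.null(test_idx)) {
    if (!is.null(n_neighbors)) {
      bal <- smote_balance(xtr, ytr, n_neighbors = n_neighbors,
                           target_ratio = target_ratio, seed = seed)
      xtr <- bal$x; ytr <- bal$y
    }
    f <- make_kopls_fitness(xtr, ytr,
                            x[test_idx, mask, drop = FALSE], y[test_idx],
                            sigma = sigma, ao = ao)
    return(f(rep(TRUE, sum(mask))))
  }
  folds <- make_stratified_folds(ytr, n_folds, seed = seed)
  yhat <- integer(length(ytr))
  for (fo in seq_len(n_folds)) {
    tr <- folds != fo
    xf <- xtr[tr, , drop = FALSE]
    yf <- ytr[tr]
    if (!is.null(n_neighbors) && min(table(yf)) > n_neighbors) {
      bal <- smote_balance(xf, yf, n_neighbors = n_neighbors,
                           target_ratio = target_ratio,
                           seed = derive_seed(seed, fo))
      xf <- bal$x; yf <- bal$y
    }
    fit <- tryCatch(kopls_fit(xf, yf, sigma = sigma, ao = ao),
                    error = function(e) NULL)
    if (is.null(fit)) return(1)
    yhat[!tr] <- predict(fit, xtr[!tr, , drop = FALSE], type = "class")
  }
  balanced_error(ytr, yhat)
}

#' Run one genetic-algorithm feature-selection search
#'
#' Simple generational GA over binary feature masks: Bernoulli
#' (`init_selection_ratio`) initialization, fitness-proportional (roulette)
#' selection on `1 - error`, single-point crossover, bitwise mutation, and
#' elitism of one, run for exactly `n_generations` generations. Fitness
#' values are cached by mask, so an identical chromosome is never
#' re-evaluated within a run. Deterministic given `config$seed`.
#'
#' @param fitness Function taking a logical mask and returning an error in
#'   \[0, 1\] (lower is better). Empty masks are scored 1 without calling it.
#' @param n_features Chromosome length (>= 2).
#' @param config A [ga_config()].
#' @return Object of class `ga_run`: `best_mask` (logical), `best_fitness`,
#'   `trace` (best-so-far fitness per generation), `n_evals`.
#' @export
run_ga <- function(fitness, n_features, config = ga_config()) {
  n_features <- assert_count(n_features, "n_features", lower = 2L)
  pop_n <- config$population_size
  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_evals <- 0L
  eval_mask <- function(mask) {
    if (!any(mask)) return(1)
    key <- rawToChar(as.raw(45L + mask)) # "-" / "." string key
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- fitness(mask)
    n_evals <<- n_evals + 1L
    cache[[key]] <- val
    val
  }
  with_seed_if(config$seed, {
    pop <- matrix(
      stats::runif(pop_n * n_features) < config$init_selection_ratio,
      nrow = pop_n
    )
    fit_vals <- apply(pop, 1, eval_mask)
    trace <- numeric(config$n_generations)
    for (gen in seq_len(config$n_generations)) {
      elite_idx <- which.min(fit_vals)
      # roulette weights: windowed inverted error (Goldberg scaling), so
      # selection pressure tracks the within-population error spread
      w <- max(fit_vals) - fit_vals
      if (all(w <= 0)) w <- rep(1, pop_n)
      n_children <- pop_n - 1L
      parents <- matrix(
        sample.int(pop_n, 2L * n_children, replace = TRUE, prob = w),
        ncol = 2L
      )
      children <- matrix(FALSE, n_children, n_features)
      for (i in seq_len(n_children)) {
        p1 <- pop[parents[i, 1], ]
        p2 <- pop[parents[i, 2], ]
        if (stats::runif(1) < config$crossover_prob) {
          cut <- sample.int(n_features - 1L, 1L)
          children[i, ] <- c(p1[seq_len(cut)], p2[(cut + 1L):n_features])
        } else {
          children[i, ] <- p1
        }
      }
      flip <- matrix(stats::runif(n_children * n_features) <
                       config$mutation_prob, n_children)
      children <- xor(children, flip)
      pop <- rbind(pop[elite_idx, , drop = FALSE], children)
      fit_vals <- c(fit_vals[elite_idx], apply(children, 1, eval_mask))
      trace[gen] <- min(fit_vals)
    }
  })
  best <- which.min(fit_vals)
  structure(
    list(best_mask = as.logical(pop[best, ]), best_fitness = fit_vals[best],
         trace = trace, n_evals = n_evals),
    class = "ga_run"
  )
}

#' Repeated GA runs and per-feature selection counts
#'
#' Runs `config$n_runs` independent GA-KOPLS selections. Each run draws a
#' fresh stratified 50% training split, rebalances it with SMOTE, and
#' evolves feature masks under a balanced-prediction-error fitness. With
#' `fitness = "test"` (the study protocol, default) the classifier trains
#' on the rebalanced half and is scored on the full original cohort
#' (`strict_holdout = TRUE` scores on the untouched half instead); with
#' `fitness = "cv"` it is scored by pooled `cv_folds`-fold cross-validation
#' inside the rebalanced training half. The per-feature tally `x_j` counts
#' the runs whose best mask includes feature `j`; `m` is the mean number of
#' features per best mask, rounded to an integer — the inputs of the
#' binomial selection-frequency test.
#'
#' @param x,y Feature matrix (columns named by feature) and 0/1 labels.
#' @param config A [ga_config()].
#' @param n_neighbors SMOTE neighbour parameter (`NULL` disables SMOTE).
#' @param target_ratio SMOTE target ratio.
#' @param sigma,ao Kernel-OPLS settings for the fitness.
#' @param fitness `"test"` or `"cv"`, see above.
#' @param cv_folds Cross-validation folds when `fitness = "cv"`.
#' @param strict_holdout Score `"test"` fitness on the untouched half.
#' @param fixed_split Use one split for all runs instead of a fresh split
#'   per run.
#' @return A tibble of class `selection_counts` (`feature_id`, `count`) with
#'   attributes `n_runs`, `n_features`, `m`, `best_masks`, `best_fitness`,
#'   `traces`.
#' @export
ga_select <- function(x, y, config = ga_config(), n_neighbors = 5,
                      target_ratio = 1, sigma = NULL, ao = 1,
                      fitness = c("test", "cv"), cv_folds = 5,
                      strict_holdout = FALSE, fixed_split = FALSE) {
  fitness <- match.arg(fitness)
  x <- as.matrix(x)
  y <- assert_binary_labels(y)
  v <- ncol(x)
  feature_id <- colnames(x)
  if (is.null(feature_id)) feature_id <- sprintf("V%03d", seq_len(v))
  masks <- matrix(FALSE, config$n_runs, v)
  fits <- numeric(config$n_runs)
  traces <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    sseed <- derive_seed(config$seed, 1L, r)
    split_seed <- if (fixed_split) derive_seed(config$seed, 1L, 0L) else sseed
    tr <- stratified_half_split(y, seed = split_seed)
    bal <- smote_list(x[tr, , drop = FALSE], y[tr], n_neighbors,
                      target_ratio, seed = sseed + 1L)
    fit_fun <- if (fitness == "cv") {
      make_kopls_cv_fitness(bal$x, bal$y, n_folds = cv_folds,
                            seed = sseed + 3L, sigma = sigma, ao = ao)
    } else {
      te <- if (strict_holdout) setdiff(seq_along(y), tr) else seq_along(y)
      make_kopls_fitness(bal$x, bal$y, x[te, , drop = FALSE], y[te],
                         sigma = sigma, ao = ao)
    }
    run <- run_ga(fit_fun, v, ga_config_update(config, seed = sseed + 2L))
    masks[r, ] <- run$best_mask
    fits[r] <- run$best_fitness
    traces[[r]] <- run$trace
  }
  counts <- tibble::tibble(feature_id = feature_id,
                           count = as.integer(colSums(masks)))
  structure(
    counts,
    n_runs = config$n_runs,
    n_features = v,
    m = as.integer(round(mean(rowSums(masks)))),
    best_masks = masks,
    best_fitness = fits,
    traces = traces,
    class = c("selection_counts", class(counts))
  )
}

smote_list <- function(x, y, n_neighbors, target_ratio, seed) {
  if (is.null(n_neighbors)) {
    list(x = x, y = y)
  } else {
    smote_balance(x, y, n_neighbors = n_neighbors,
                  target_ratio = target_ratio, seed = seed)
  }
}

#' @export
print.selection_counts <- function(x, ...) {
  cat(sprintf(
    "Selection counts over %d GA runs (v = %d features, m = %d selected/run)\n",
    attr(x, "n_runs"), attr(x, "n_features"), attr(x, "m")
  ))
  NextMethod()
}
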