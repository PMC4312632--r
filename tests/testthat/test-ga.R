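test_that("GA runs are deterministic and respect elitism", {
  fitness <- function(mask) sum(mask) / length(mask)
  cfg <- ga_config(population_size = 10, n_generations = 15, seed = 4)
  a <- run_ga(fitness, 30, cfg)
  b <- run_ga(fitness, 30, cfg)
  expect_identical(a, b)
  # elitism: population best never worsens across generations
  expect_true(all(diff(a$trace) <= 0))
  expect_equal(a$best_fitness, min(a$trace))
})

test_that("the popcount toy collapses masks toward empty", {
  fitness <- function(mask) sum(mask) / length(mask)
  cfg <- ga_config(population_size = 20, n_generations = 40,
                   init_selection_ratio = 0.3, seed = 9)
  run <- run_ga(fitness, 50, cfg)
  expect_lt(sum(run$best_mask), 0.3 * 50 / 2)
  expect_lt(run$best_fitness, 0.15)
})

test_that("empty masks score worst without raising", {
  exploding <- function(mask) {
    if (!any(mask)) stop("should never be called on empty masks")
    0.5
  }
  cfg <- ga_config(population_size = 6, n_generations = 5,
                   init_selection_ratio = 0.02, seed = 2)
  expect_no_error(run <- run_ga(exploding, 10, cfg))
  expect_identical(evaluate_fitness(rep(FALSE, 5), matrix(rnorm(40), 8),
                                    rep(c(0L, 1L), 4)), 1)
})

test_that("fitness caching never re-evaluates a mask", {
  calls <- new.env(); calls$n <- 0L; calls$seen <- character(0)
  fitness <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    expect_false(key %in% calls$seen)
    calls$seen <- c(calls$seen, key)
    calls$n <- calls$n + 1L
    sum(mask) / length(mask)
  }
  run <- run_ga(fitness, 12, ga_config(population_size = 8,
                                       n_generations = 10, seed = 3))
  expect_identical(run$n_evals, calls$n)
  expect_lte(run$n_evals, 8 + 10 * 7)
})

test_that("compiled and reference fitness paths agree exactly", {
  cohort <- small_cohort(seed = 8)
  xy <- assemble_matrix(sum_normalize(cohort$table))
  tr <- koplstrat:::stratified_half_split(xy$y, seed = 1)
  bal <- smote_balance(xy$x[tr, ], xy$y[tr], n_neighbors = 3, seed = 2)
  for (ao in 0:2) {
    fr <- koplstrat:::make_kopls_fitness(bal$x, bal$y, xy$x, xy$y,
                                         ao = ao, engine = "r")
    fc <- koplstrat:::make_kopls_fitness(bal$x, bal$y, xy$x, xy$y,
                                         ao = ao, engine = "cpp")
    set.seed(ao)
    for (i in 1:10) {
      mask <- runif(ncol(xy$x)) < 0.3
      if (!any(mask)) mask[1] <- TRUE
      expect_equal(fc(mask), fr(mask), tolerance = 1e-12)
    }
  }
})

test_that("masks of planted features beat random masks of equal size", {
  cohort <- small_cohort(seed = 10, n0 = 60, n1 = 24, v = 25, k = 3)
  xy <- assemble_matrix(sum_normalize(cohort$table))
  truth <- match(cohort$truth$feature_id, colnames(xy$x))
  tr <- koplstrat:::stratified_half_split(xy$y, seed = 3)
  bal <- smote_balance(xy$x[tr, ], xy$y[tr], n_neighbors = 3, seed = 4)
  f <- koplstrat:::make_kopls_fitness(bal$x, bal$y, xy$x, xy$y, ao = 1)
  planted <- rep(FALSE, 25); planted[truth] <- TRUE
  err_planted <- f(planted)
  set.seed(11)
  wins <- vapply(1:20, function(i) {
    rand <- rep(FALSE, 25)
    rand[sample(setdiff(1:25, truth), 3)] <- TRUE
    f(rand) > err_planted
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("label-permuted fitness sits near chance", {
  cohort <- small_cohort(seed = 12, n0 = 40, n1 = 40, v = 15, k = 0)
  xy <- assemble_matrix(sum_normalize(cohort$table))
  set.seed(2)
  errs <- vapply(1:15, function(i) {
    yp <- sample(xy$y)
    tr <- koplstrat:::stratified_half_split(yp, seed = i)
    f <- koplstrat:::make_kopls_fitness(xy$x[tr, ], yp[tr], xy$x, yp, ao = 1)
    f(runif(15) < 0.4)
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.15)
})

test_that("selection counts obey the counting identities", {
  cohort <- small_cohort(seed = 13)
  xy <- assemble_matrix(sum_normalize(cohort$table))
  cfg <- ga_config(population_size = 8, n_generations = 5, n_runs = 3, seed = 5)
  counts <- ga_select(xy$x, xy$y, cfg, n_neighbors = 3)
  masks <- attr(counts, "best_masks")
  expect_identical(sum(counts$count), as.integer(sum(masks)))
  expect_identical(attr(counts, "m"),
                   as.integer(round(mean(rowSums(masks)))))
  expect_true(all(counts$count >= 0 & counts$count <= 3))
  expect_identical(attr(counts, "n_features"), ncol(xy$x))
  # single run: counts are the best mask itself
  one <- ga_select(xy$x, xy$y, ga_config_update(cfg, n_runs = 1L),
                   n_neighbors = 3)
  expect_identical(one$count, as.integer(attr(one, "best_masks")[1, ]))
  # every per-run trace is non-increasing (elitism invariant)
  for (tr in attr(counts, "traces")) expect_true(all(diff(tr) <= 0))
  expect_s3_class(autoplot(counts), "ggplot")
})

test_that("configuration validation rejects bad values", {
  expect_error(ga_config(population_size = 1), "integer")
  expect_error(ga_config(crossover_prob = 1.5), "0, 1")
  expect_error(ga_config(mutation_prob = -0.1), ">=")
})
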