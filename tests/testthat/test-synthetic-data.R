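test_that("cohort generation is deterministic and matches the spec shape", {
  spec <- synthetic_spec(seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  x <- peak_intensities(a$table)
  expect_identical(dim(x), c(295L, 135L))
  expect_identical(sum(a$table$label == 0), 238L)
  expect_identical(sum(a$table$label == 1), 57L)
  expect_identical(nrow(a$truth), 4L)
  expect_true(all(a$truth$direction == 1L))
  expect_true(all(x > 0))
  expect_true("IS" %in% peak_features(a$table)$feature_id)
})

test_that("different seeds give different cohorts", {
  a <- generate_cohort(synthetic_spec(seed = 1))
  b <- generate_cohort(synthetic_spec(seed = 2))
  expect_false(identical(peak_intensities(a$table), peak_intensities(b$table)))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_informative = 200), "exceeds")
  expect_error(synthetic_spec(n_class0 = 0), "integer")
  expect_error(synthetic_spec(log2_effect = Inf), "finite")
  expect_error(synthetic_spec(cv_noise = 0), ">")
  expect_error(generate_cohort(list()), "synthetic_spec")
  expect_error(
    generate_cohort(synthetic_spec(n_informative = 2), direction = c(1, 2)),
    "direction"
  )
})

test_that("the internal standard is near-constant at its stated coordinates", {
  cohort <- generate_cohort(synthetic_spec(seed = 11))
  ft <- peak_features(cohort$table)
  is_row <- ft[ft$feature_id == "IS", ]
  expect_equal(is_row$mz, 200.0473, tolerance = 1e-6)
  expect_equal(is_row$rt_min, 1.0, tolerance = 1e-6)
  x <- peak_intensities(cohort$table)
  cv <- sd(x[, "IS"]) / mean(x[, "IS"])
  expect_lt(cv, 0.05)
})

test_that("a null cohort carries no class signal", {
  cohort <- generate_cohort(synthetic_spec(
    n_class0 = 100, n_class1 = 100, n_features = 30, n_informative = 0,
    include_internal_standard = FALSE, seed = 5
  ))
  expect_identical(nrow(cohort$truth), 0L)
  x <- peak_intensities(cohort$table)
  y <- cohort$table$label
  p <- apply(x, 2, function(col) wilcoxon_rank_sum(col[y == 1], col[y == 0]))
  # type-I behaviour: about alpha of the features reject
  expect_lt(mean(p < 0.05), 0.25)
  expect_gt(min(p), 0) # no degenerate zero P values
})

test_that("planted effects give the advertised Wilcoxon power", {
  # log2_effect = 2 at 200 per class: informative features reject at
  # P < 0.05 in >= 95% of seeds (Monte-Carlo over 100 seeds, small v)
  hits <- vapply(1:100, function(s) {
    cohort <- generate_cohort(synthetic_spec(
      n_class0 = 200, n_class1 = 200, n_features = 8, n_informative = 2,
      log2_effect = 2, include_internal_standard = FALSE, seed = s
    ))
    x <- peak_intensities(cohort$table)
    y <- cohort$table$label
    all(vapply(cohort$truth$feature_id, function(f) {
      wilcoxon_rank_sum(x[y == 1, f], x[y == 0, f]) < 0.05
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("clinical tables hit configured group means and validate input", {
  expect_error(generate_clinical_table(10, rep(0, 5)), "length")
  big <- generate_clinical_table(4000, rep(c(0, 1), each = 2000), seed = 3)
  # sample means within 2 SE of the configured targets
  se0 <- 8.50 / sqrt(2000)
  se1 <- 9.49 / sqrt(2000)
  expect_lt(abs(mean(big$age[big$group == 0]) - 71.55), 2 * se0)
  expect_lt(abs(mean(big$age[big$group == 1]) - 67.11), 2 * se1)
  expect_true(all(big$fatty_liver %in% 0:1))
})

test_that("equal-group clinical covariates behave as a null for the t-test", {
  p <- vapply(1:200, function(s) {
    cl <- generate_clinical_table(
      60, rep(c(0, 1), each = 30), seed = s,
      continuous = list(age = c(70, 9, 70, 9)), binary = list()
    )
    summarize_continuous(cl$age, cl$group)$p_value
  }, numeric(1))
  # roughly uniform: mean near 0.5, rejection rate near alpha
  expect_lt(abs(mean(p) - 0.5), 0.1)
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p < 0.5), 0.35)
})
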