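make_table <- function(x, rt, mz, label = NULL) {
  peak_table(
    x,
    tibble::tibble(
      feature_id = sprintf("F%02d", seq_along(rt)), rt_min = rt, mz = mz
    ),
    sample_id = sprintf("s%02d", seq_len(nrow(x))),
    label = label
  )
}

test_that("internal-standard removal drops exactly the matching window", {
  x <- matrix(runif(12, 1, 10), 3, 4)
  tab <- make_table(x, rt = c(1.0, 2.0, 3.0, 1.05), mz = c(200.0473, 300, 400, 200.012))
  out <- suppressMessages(remove_internal_standard(tab, 200.0473, 1.0))
  expect_identical(peak_features(out)$feature_id, c("F02", "F03", "F04"))
  # widen the window: the second candidate at (1.05, 200.012) matches too
  out2 <- suppressMessages(
    remove_internal_standard(tab, 200.0473, 1.0, mz_tol = 0.05, rt_tol = 0.1)
  )
  expect_identical(ncol(peak_intensities(out2)), 2L)
})

test_that("no match warns and leaves the table unchanged", {
  x <- matrix(runif(6, 1, 10), 3, 2)
  tab <- make_table(x, rt = c(5, 6), mz = c(300, 400))
  expect_warning(out <- remove_internal_standard(tab, 200.0473, 1.0), "unchanged")
  expect_identical(peak_intensities(out), peak_intensities(tab))
})

test_that("removing every feature is an error", {
  x <- matrix(runif(3, 1, 10), 3, 1)
  tab <- make_table(x, rt = 1.0, mz = 200.0473)
  expect_error(remove_internal_standard(tab, 200.0473, 1.0), "every feature")
})

test_that("generator cohorts lose exactly one feature to IS removal", {
  cohort <- generate_cohort(synthetic_spec(seed = 2))
  out <- suppressMessages(remove_internal_standard(cohort$table))
  expect_identical(ncol(peak_intensities(out)), 134L)
  xy <- assemble_matrix(sum_normalize(out))
  expect_identical(dim(xy$x), c(295L, 134L))
  expect_identical(length(xy$y), 295L)
})

test_that("sum normalization has the stated arithmetic and invariances", {
  tab <- make_table(matrix(c(2, 3, 5), 1, 3), rt = 1:3, mz = 101:103)
  out <- sum_normalize(tab)
  expect_equal(unname(peak_intensities(out)[1, ]), c(0.2, 0.3, 0.5))
  # idempotence
  expect_equal(peak_intensities(sum_normalize(out)), peak_intensities(out))
  # row sums exactly one on random positive matrices, scale invariance
  x <- matrix(rexp(60) + 0.01, 6, 10)
  t1 <- sum_normalize(make_table(x, rt = 1:10, mz = 101:110))
  expect_equal(unname(rowSums(peak_intensities(t1))), rep(1, 6),
               tolerance = 1e-12)
  t2 <- sum_normalize(make_table(x * runif(6, 0.5, 20), rt = 1:10, mz = 101:110))
  expect_equal(peak_intensities(t1), peak_intensities(t2))
})

test_that("zero-total samples are reported by name", {
  x <- rbind(c(1, 2), c(0, 0))
  tab <- make_table(x, rt = 1:2, mz = 101:102)
  expect_error(sum_normalize(tab), "s02")
})

test_that("pipeline order matters: removal before normalization", {
  x <- matrix(c(5, 1, 1, 5, 1, 1), 2, 3, byrow = TRUE)
  tab <- make_table(x, rt = c(1.0, 5, 6), mz = c(200.0473, 300, 400))
  a <- sum_normalize(suppressMessages(remove_internal_standard(tab, 200.0473, 1.0)))
  b <- suppressMessages(remove_internal_standard(sum_normalize(tab), 200.0473, 1.0))
  expect_false(isTRUE(all.equal(peak_intensities(a), peak_intensities(b))))
  expect_equal(unname(rowSums(peak_intensities(a))), rep(1, 2))
})

test_that("assemble_matrix validates labels and preserves order", {
  x <- matrix(runif(8, 1, 2), 4, 2)
  tab <- make_table(x, rt = 1:2, mz = 101:102, label = c(0, 1, NA, 1))
  expect_error(assemble_matrix(tab), "s03")
  tab2 <- make_table(x, rt = 1:2, mz = 101:102, label = c(0, 1, 0, 1))
  xy <- assemble_matrix(tab2)
  expect_identical(xy$y, c(0L, 1L, 0L, 1L))
  expect_identical(rownames(xy$x), tab2$sample_id)
  # permuting samples permutes (x, y) identically
  perm <- c(3, 1, 4, 2)
  xy_p <- assemble_matrix(new_tab <- peak_table(
    x[perm, ], peak_features(tab2), sample_id = tab2$sample_id[perm],
    label = tab2$label[perm]
  ))
  expect_identical(xy_p$x, xy$x[perm, ])
  expect_identical(xy_p$y, xy$y[perm])
  expect_error(assemble_matrix(tab2[0, ]), "empty")
})

test_that("peak tables round-trip through the TSV dialect", {
  cohort <- generate_cohort(synthetic_spec(
    n_class0 = 6, n_class1 = 3, n_features = 5, n_informative = 1, seed = 9
  ))
  dir <- withr::local_tempdir()
  pt <- file.path(dir, "peaks.tsv")
  lt <- file.path(dir, "labels.tsv")
  write_peak_table(cohort$table, pt, lt)
  back <- read_peak_table(pt, lt)
  expect_equal(peak_intensities(back), peak_intensities(cohort$table))
  expect_equal(peak_features(back), peak_features(cohort$table))
  expect_identical(back$label, cohort$table$label)
})
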