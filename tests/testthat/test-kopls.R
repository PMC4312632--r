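test_that("gaussian kernel matches hand-computed pairwise distances", {
  x1 <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE)
  x2 <- matrix(c(1, 1, 2, 0), 2, 2, byrow = TRUE)
  sigma <- 1.3
  k <- gaussian_kernel(x1, x2, sigma)
  for (i in 1:3) for (j in 1:2) {
    d2 <- sum((x1[i, ] - x2[j, ])^2)
    expect_equal(k[i, j], exp(-d2 / (2 * sigma^2)), tolerance = 1e-12)
  }
  # unit diagonal / symmetry on a single input
  ks <- gaussian_kernel(x1, sigma = sigma)
  expect_equal(diag(ks), rep(1, 3))
  expect_equal(ks, t(ks))
  # sigma -> large: entries -> 1
  expect_true(all(abs(gaussian_kernel(x1, sigma = 1e6) - 1) < 1e-9))
  expect_error(gaussian_kernel(x1, sigma = 0), "sigma")
  expect_error(gaussian_kernel(x1, matrix(0, 2, 3), sigma = 1), "dimensions")
})

test_that("gaussian kernels are positive semi-definite", {
  set.seed(4)
  for (i in 1:10) {
    x <- matrix(rnorm(15 * 4), 15)
    k <- gaussian_kernel(x, sigma = runif(1, 0.3, 3))
    expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("kernel centering zeroes row and column means and is idempotent", {
  set.seed(8)
  x <- matrix(rnorm(50), 10)
  k <- tcrossprod(x)
  cen <- center_kernel_train(k)
  expect_lt(max(abs(rowMeans(cen$kc))), 1e-10)
  expect_lt(max(abs(colMeans(cen$kc))), 1e-10)
  # already-centered kernel is unchanged
  cen2 <- center_kernel_train(cen$kc)
  expect_equal(cen2$kc, cen$kc, tolerance = 1e-12)
  # rank-one constant kernel centers to zero
  expect_lt(max(abs(center_kernel_train(matrix(1, 6, 6))$kc)), 1e-12)
  expect_error(center_kernel_train(matrix(1, 2, 3)), "square")
})

test_that("test-kernel centering is consistent with the training side", {
  set.seed(9)
  x <- matrix(rnorm(40), 8)
  k <- tcrossprod(x)
  cen <- center_kernel_train(k)
  # test set equal to the training set reproduces Kc
  expect_equal(center_kernel_test(k, cen$stats), cen$kc, tolerance = 1e-12)
  # single test point equal to training point j gives row j of Kc
  expect_equal(
    drop(center_kernel_test(k[3, , drop = FALSE], cen$stats)),
    cen$kc[3, ], tolerance = 1e-12
  )
  # linear kernel: centering in kernel space == centering features first
  xt <- matrix(rnorm(20), 4)
  xc <- sweep(x, 2, colMeans(x))
  xtc <- sweep(xt, 2, colMeans(x))
  expect_equal(center_kernel_test(tcrossprod(xt, x), cen$stats),
               tcrossprod(xtc, xc), tolerance = 1e-10)
  expect_error(center_kernel_test(matrix(0, 2, 5), cen$stats), "dimension")
})

test_that("linear-kernel K-OPLS reproduces primal OPLS", {
  set.seed(11)
  for (i in 1:5) {
    x <- matrix(rnorm(30 * 10), 30)
    y <- rep(c(0L, 1L), each = 15)
    xt <- matrix(rnorm(7 * 10), 7)
    for (ao in 0:2) {
      fit <- kopls_fit(x, y, ao = ao, kernel = "linear")
      o <- oracle_primal_opls(x, y, ao, xt)
      expect_equal(fit$fitted, o$fitted, tolerance = 1e-8)
      expect_equal(predict(fit, xt), o$pred, tolerance = 1e-8)
      expect_equal(fit$core$r2y, o$r2y, tolerance = 1e-8)
    }
  }
})

test_that("model structure invariants hold", {
  set.seed(12)
  x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
  y <- rep(c(0L, 1L), each = 20)
  fit <- kopls_fit(x, y, sigma = 2, ao = 3)
  # predictive score orthogonal to every orthogonal score
  expect_lt(max(abs(crossprod(fit$core$t_p, fit$core$scores_ortho))) /
              sqrt(sum(fit$core$t_p^2)), 1e-8)
  # prediction on training data reproduces the stored fitted values
  expect_equal(predict(fit, x), fit$fitted, tolerance = 1e-8)
  # duplicated test rows give duplicated predictions
  pr <- predict(fit, x[c(1, 1, 5), ])
  expect_equal(pr[1], pr[2])
  # adding orthogonal components never decreases training R2Y
  r2 <- vapply(0:3, function(a) kopls_fit(x, y, sigma = 2, ao = a)$core$r2y,
               numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
  # r2x, r2y in [0, 1]
  expect_true(all(c(fit$core$r2x, fit$core$r2y) >= 0 &
                    c(fit$core$r2x, fit$core$r2y) <= 1))
})

test_that("separable data classifies perfectly with ao = 0", {
  x <- rbind(matrix(0.1 * rnorm(20), 10), matrix(5 + 0.1 * rnorm(20), 10))
  y <- rep(c(0L, 1L), each = 10)
  fit <- kopls_fit(x, y, ao = 0, kernel = "linear")
  expect_identical(as.integer(fit$fitted >= 0.5), y)
})

test_that("degenerate fits are rejected", {
  x <- matrix(rnorm(20), 10)
  expect_error(kopls_fit(x, rep(0L, 10), sigma = 1), "variance|classes|0/1")
  expect_error(kopls_fit(x, rep(c(0L, 1L), 5), sigma = 1, ao = 10), "smaller")
})

test_that("cross-validated fit statistics match a hand-rolled fold loop", {
  cohort <- small_cohort(seed = 21)
  xy <- assemble_matrix(sum_normalize(cohort$table))
  st <- kopls_fit_stats(xy$x, xy$y, sigma = 0.05, ao = 1, n_folds = 4, seed = 3)
  # manual fold loop with the same fold assignment
  folds <- koplstrat:::make_stratified_folds(xy$y, 4, seed = 3)
  press <- 0
  for (f in 1:4) {
    tr <- folds != f
    fit <- kopls_fit(xy$x[tr, ], xy$y[tr], sigma = 0.05, ao = 1)
    press <- press + sum((xy$y[!tr] - predict(fit, xy$x[!tr, ]))^2)
  }
  expect_equal(st$q2y, 1 - press / sum((xy$y - mean(xy$y))^2),
               tolerance = 1e-10)
  # a perfect training fit has r2y = 1 (separable linear toy)
  xsep <- rbind(matrix(rnorm(20, 0, 0.05), 10), matrix(rnorm(20, 9, 0.05), 10))
  ysep <- rep(c(0L, 1L), each = 10)
  expect_equal(kopls_fit(xsep, ysep, ao = 0, kernel = "linear")$core$r2y, 1,
               tolerance = 1e-3)
  expect_error(
    kopls_fit_stats(xy$x, xy$y, sigma = 1, n_folds = 100),
    "minority"
  )
})

test_that("a mean-only predictor gives non-positive Q2Y", {
  # constant features carry no information, so CV prediction cannot beat
  # the mean and Q2Y <= 0
  set.seed(31)
  x <- matrix(rnorm(60 * 5), 60)
  y <- rep(c(0L, 1L), each = 30)
  st <- kopls_fit_stats(x, y, sigma = 1e5, ao = 0, n_folds = 5, seed = 1)
  expect_lte(st$q2y, 0.05)
})

test_that("ACCV grid search finds separable data and stays in range", {
  set.seed(13)
  x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
  y <- rep(c(0L, 1L), each = 20)
  tune <- kopls_tune(x, y, sigma_grid = c(1, 3), ao_grid = 0:1,
                     n_folds = 5, seed = 2)
  expect_equal(tune$best_accv, 1)
  expect_true(all(tune$surface$accv >= 0 & tune$surface$accv <= 1))
  # ties break toward smaller ao then smaller sigma
  first <- tune$surface[order(-tune$surface$accv, tune$surface$ao,
                              tune$surface$sigma), ][1, ]
  expect_identical(c(tune$best_sigma, tune$best_ao),
                   c(first$sigma, first$ao))
  expect_error(kopls_tune(x, y, sigma_grid = numeric(0)), "nonempty")
})

test_that("permuted labels give chance-level ACCV", {
  cohort <- small_cohort(seed = 17, n0 = 30, n1 = 30, k = 0)
  xy <- assemble_matrix(sum_normalize(cohort$table))
  set.seed(5)
  yperm <- sample(xy$y)
  tune <- kopls_tune(xy$x, yperm, sigma_grid = c(0.05), ao_grid = 0:1,
                     n_folds = 5, seed = 2)
  # majority rate is 0.5 here; allow generous binomial noise
  expect_lt(tune$best_accv, 0.75)
})

test_that("tidy / glance / autoplot methods work", {
  set.seed(14)
  x <- rbind(matrix(rnorm(30), 15), matrix(rnorm(30, 2), 15))
  y <- rep(c(0L, 1L), each = 15)
  fit <- kopls_fit(x, y, sigma = 2, ao = 1)
  td <- tidy(fit)
  expect_named(td, c("sample", "label", ".fitted", "t_p", "t_o1"))
  expect_identical(nrow(td), 30L)
  gl <- glance(fit)
  expect_identical(gl$ao, 1L)
  expect_s3_class(autoplot(fit), "ggplot")
  tune <- kopls_tune(x, y, sigma_grid = c(1, 2), ao_grid = 0:1,
                     n_folds = 3, seed = 1)
  expect_s3_class(autoplot(tune), "ggplot")
})
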