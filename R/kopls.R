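#' Gaussian (RBF) kernel matrix
#'
#' `K[i, j] = exp(-||x1_i - x2_j||^2 / (2 sigma^2))`. With a single input the
#' matrix is symmetric with a unit diagonal.
#'
#' @param x1 Numeric matrix (rows = samples).
#' @param x2 Optional second matrix with the same number of columns;
#'   defaults to `x1`.
#' @param sigma Positive kernel width.
#' @return The `nrow(x1) x nrow(x2)` kernel matrix.
#' @export
gaussian_kernel <- function(x1, x2 = NULL, sigma) {
  assert_scalar_number(sigma, "sigma", lower = 0, strict = TRUE)
  x1 <- as.matrix(x1)
  same <- is.null(x2)
  x2 <- if (same) x1 else as.matrix(x2)
  if (ncol(x1) != ncol(x2)) rlang::abort("feature dimensions must match")
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  d2 <- pmax(d2, 0)
  if (same) diag(d2) <- 0
  exp(-d2 / (2 * sigma^2))
}

linear_kernel <- function(x1, x2 = NULL) {
  x1 <- as.matrix(x1)
  x2 <- if (is.null(x2)) x1 else as.matrix(x2)
  tcrossprod(x1, x2)
}

compute_kernel <- function(x1, x2 = NULL, sigma, kernel = "gaussian") {
  switch(kernel,
    gaussian = gaussian_kernel(x1, x2, sigma),
    linear = linear_kernel(x1, x2),
    rlang::abort(sprintf("unknown kernel '%s'", kernel))
  )
}

#' Center a training kernel matrix
#'
#' Double-centering `Kc = (I - 11'/n) K (I - 11'/n)`, equivalent to
#' mean-centering the samples in feature space. The returned statistics are
#' what [center_kernel_test()] needs to center test-vs-train cross kernels
#' consistently.
#'
#' @param k Square symmetric kernel matrix.
#' @return List with `kc` (centered kernel) and `stats` (training column
#'   means and grand mean).
#' @export
center_kernel_train <- function(k) {
  k <- as.matrix(k)
  if (nrow(k) != ncol(k)) rlang::abort("training kernel must be square")
  col_means <- colMeans(k)
  grand_mean <- mean(k)
  kc <- k - outer(rep(1, nrow(k)), col_means) -
    outer(col_means, rep(1, nrow(k))) + grand_mean
  list(kc = kc, stats = list(col_means = col_means, grand_mean = grand_mean))
}

#' Center a test-vs-train cross kernel
#'
#' @param k_test_train `n_test x n_train` kernel of test points against the
#'   training points.
#' @param stats Centering statistics from [center_kernel_train()].
#' @return The centered cross kernel.
#' @export
center_kernel_test <- function(k_test_train, stats) {
  k <- as.matrix(k_test_train)
  if (ncol(k) != length(stats$col_means)) {
    rlang::abort("cross kernel has wrong training dimension")
  }
  k - outer(rep(1, nrow(k)), stats$col_means) -
    outer(rowMeans(k), rep(1, ncol(k))) + stats$grand_mean
}

#' Fit a kernel-OPLS model on a centered kernel
#'
#' Estimates one predictive component and `ao` Y-orthogonal components for a
#' single binary response, entirely in kernel space. The recursion is the
#' kernelized single-response orthogonal-PLS recursion (see the methods
#' vignette for the derivation); with a linear kernel it reproduces primal
#' OPLS exactly, which is the package's binding correctness oracle.
#'
#' @param kc Centered training kernel from [center_kernel_train()].
#' @param y Numeric 0/1 response.
#' @param ao Number of Y-orthogonal components (>= 0).
#' @return A list (class `kopls_kernel_fit`) with the component scores and
#'   the statistics needed for prediction; `fitted` holds the training
#'   fitted values on the response scale.
#' @export
fit_kopls_kernel <- function(kc, y, ao = 1) {
  kc <- as.matrix(kc)
  n <- nrow(kc)
  if (ncol(kc) != n) rlang::abort("`kc` must be square")
  if (length(y) != n) rlang::abort("`y` length must match the kernel")
  ao <- assert_count(ao, "ao", lower = 0L)
  if (ao >= n) rlang::abort("`ao` must be smaller than the sample count")
  y <- as.numeric(y)
  if (stats::var(y) == 0) rlang::abort("response has zero variance")
  y_mean <- mean(y)
  yc <- y - y_mean
  s <- drop(crossprod(yc, kc %*% yc))
  if (!is.finite(s) || s <= 0) {
    rlang::abort("degenerate kernel: y' K y is not positive")
  }
  u <- yc / sqrt(s)

  k_i1 <- kc # current cross kernel vs original space, rows deflated
  k_ii <- kc # current doubly-deflated kernel
  comps <- list()
  for (i in seq_len(ao)) {
    t_i <- drop(k_i1 %*% u)
    tt <- sum(t_i^2)
    to_raw <- drop(k_ii %*% t_i) / tt - t_i
    to_norm <- sqrt(sum(to_raw^2))
    if (!is.finite(to_norm) || to_norm < 1e-12) break # nothing orthogonal left
    to <- to_raw / to_norm
    a_i <- drop(crossprod(k_i1, to))
    b_i <- drop(k_ii %*% to)
    xvar <- drop(crossprod(to, b_i))
    comps[[i]] <- list(t = t_i, tt = tt, to = to, to_norm = to_norm,
                       a = a_i, b = b_i, xvar = xvar)
    k_i1 <- k_i1 - tcrossprod(to, a_i)
    k_ii <- k_ii - tcrossprod(to, b_i) - tcrossprod(b_i, to) +
      xvar * tcrossprod(to)
  }
  t_p <- drop(k_i1 %*% u)
  ttp <- sum(t_p^2)
  c_coef <- sum(yc * t_p) / ttp
  fitted_c <- c_coef * t_p
  r2y <- 1 - sum((yc - fitted_c)^2) / sum(yc^2)
  trace_kc <- sum(diag(kc))
  xvar_p <- drop(crossprod(t_p, k_ii %*% t_p)) / ttp
  r2x <- (sum(vapply(comps, `[[`, 0, "xvar")) + xvar_p) / trace_kc
  structure(
    list(
      u = u, comps = comps, ao = length(comps),
      t_p = t_p, tt_p = ttp, c_coef = c_coef, y_mean = y_mean,
      fitted = fitted_c + y_mean, r2y = r2y, r2x = r2x,
      scores_ortho = if (length(comps)) {
        do.call(cbind, lapply(comps, `[[`, "to"))
      } else {
        matrix(0, n, 0)
      }
    ),
    class = "kopls_kernel_fit"
  )
}

predict_kopls_kernel <- function(core, kte_c) {
  kte_i1 <- as.matrix(kte_c)
  kte_ii <- kte_i1
  to_test <- matrix(0, nrow(kte_i1), core$ao)
  i <- 0L
  for (comp in core$comps) {
    i <- i + 1L
    t_te <- drop(kte_i1 %*% core$u)
    to_te <- (drop(kte_ii %*% comp$t) / comp$tt - t_te) / comp$to_norm
    to_test[, i] <- to_te
    kte_i1 <- kte_i1 - tcrossprod(to_te, comp$a)
    m <- kte_ii - tcrossprod(to_te, comp$b)
    kte_ii <- m - tcrossprod(drop(m %*% comp$to), comp$to)
  }
  t_te <- drop(kte_i1 %*% core$u)
  list(response = core$c_coef * t_te + core$y_mean,
       t_p = t_te, t_o = to_test)
}

#' Fit a kernel-OPLS classifier
#'
#' High-level interface: builds the (Gaussian or linear) kernel from the
#' feature matrix, centers it, and fits the kernel-OPLS model. Class
#' decisions use the 0/1 response coding with a 0.5 threshold.
#'
#' @param x Numeric samples x features matrix (or data frame of numeric
#'   columns).
#' @param y 0/1 labels (1 = excess syndrome).
#' @param sigma Gaussian kernel width; `NULL` uses the median pairwise
#'   distance heuristic.
#' @param ao Number of Y-orthogonal components.
#' @param kernel `"gaussian"` or `"linear"` (the linear kernel exists for
#'   the primal-OPLS equivalence oracle).
#' @return An object of class `kopls`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' y <- rep(c(0, 1), each = 20)
#' fit <- kopls_fit(x, y, sigma = 2, ao = 1)
#' table(predict(fit, x, type = "class"), y)
kopls_fit <- function(x, y, sigma = NULL, ao = 1,
                      kernel = c("gaussian", "linear")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- assert_binary_labels(y)
  if (nrow(x) != length(y)) rlang::abort("`x` rows must match `y` length")
  if (is.null(sigma) && kernel == "gaussian") sigma <- median_sigma(x)
  k <- compute_kernel(x, sigma = sigma, kernel = kernel)
  cen <- center_kernel_train(k)
  core <- fit_kopls_kernel(cen$kc, y, ao)
  structure(
    list(x_train = x, y = y, sigma = sigma, kernel = kernel,
         center_stats = cen$stats, core = core,
         fitted = core$fitted, ao = core$ao),
    class = "kopls"
  )
}

# Median pairwise Euclidean distance; a standard RBF width heuristic.
median_sigma <- function(x, max_n = 500L) {
  x <- as.matrix(x)
  if (nrow(x) > max_n) x <- x[seq(1, nrow(x), length.out = max_n), , drop = FALSE]
  d <- stats::median(stats::dist(x))
  if (!is.finite(d) || d <= 0) 1 else d
}

#' Predict from a kernel-OPLS model
#'
#' @param object A [kopls_fit()] object.
#' @param newdata Feature matrix with the training columns.
#' @param type `"response"` (continuous score), `"class"` (0/1 decision at
#'   0.5), or `"scores"` (predictive and orthogonal score tibble).
#' @param ... Unused.
#' @return Numeric vector, integer vector, or tibble according to `type`.
#' @export
predict.kopls <- function(object, newdata,
                          type = c("response", "class", "scores"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x_train)) {
    rlang::abort("`newdata` must have the training feature columns")
  }
  kte <- compute_kernel(newdata, object$x_train,
                        sigma = object$sigma, kernel = object$kernel)
  ktec <- center_kernel_test(kte, object$center_stats)
  pred <- predict_kopls_kernel(object$core, ktec)
  switch(type,
    response = pred$response,
    class = as.integer(pred$response >= 0.5),
    scores = {
      out <- tibble::tibble(t_p = pred$t_p)
      if (object$core$ao > 0) {
        colnames(pred$t_o) <- paste0("t_o", seq_len(object$core$ao))
        out <- dplyr::bind_cols(out, tibble::as_tibble(pred$t_o))
      }
      out
    }
  )
}

#' Training and cross-validated fit statistics
#'
#' `r2y` is the explained response variation of the full-data fit, `r2x` the
#' explained fraction of the centered-kernel trace, and `q2y = 1 -
#' PRESS/SS_tot` from stratified `n_folds` cross-validation.
#'
#' @inheritParams kopls_fit
#' @param n_folds Number of stratified CV folds.
#' @param seed Seed for the fold assignment.
#' @return One-row tibble with `r2x`, `r2y`, `q2y`.
#' @export
kopls_fit_stats <- function(x, y, sigma = NULL, ao = 1, n_folds = 10,
                            kernel = "gaussian", seed = 1) {
  x <- as.matrix(x)
  y <- assert_binary_labels(y)
  if (n_folds > min(table(y))) {
    rlang::abort("`n_folds` exceeds the minority-class count")
  }
  if (is.null(sigma) && kernel == "gaussian") sigma <- median_sigma(x)
  fit <- kopls_fit(x, y, sigma = sigma, ao = ao, kernel = kernel)
  folds <- make_stratified_folds(y, n_folds, seed = seed)
  press <- 0
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    sub <- kopls_fit(x[tr, , drop = FALSE], y[tr],
                     sigma = sigma, ao = ao, kernel = kernel)
    yhat <- predict(sub, x[!tr, , drop = FALSE])
    press <- press + sum((y[!tr] - yhat)^2)
  }
  tibble::tibble(
    r2x = fit$core$r2x,
    r2y = fit$core$r2y,
    q2y = 1 - press / sum((y - mean(y))^2)
  )
}

#' Cross-validated (sigma, Ao) grid search
#'
#' Computes the accuracy of classification under cross-validation (ACCV) for
#' every combination of kernel width and Y-orthogonal component count, with
#' one fixed stratified fold assignment shared across the grid. ACCV is the
#' pooled accuracy of the held-out class decisions. Ties are broken toward
#' the smaller `ao`, then the smaller `sigma`.
#'
#' @inheritParams kopls_fit_stats
#' @param sigma_grid Positive kernel widths to try.
#' @param ao_grid Y-orthogonal component counts to try.
#' @return An object of class `kopls_tune`: list with the ACCV `surface`
#'   tibble (`sigma`, `ao`, `accv`), `best_sigma`, `best_ao`.
#' @export
kopls_tune <- function(x, y, sigma_grid = c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5),
                       ao_grid = 0:5, n_folds = 10, seed = 1,
                       kernel = "gaussian") {
  if (!length(sigma_grid) || !length(ao_grid)) {
    rlang::abort("parameter grids must be nonempty")
  }
  x <- as.matrix(x)
  y <- assert_binary_labels(y)
  folds <- make_stratified_folds(y, n_folds, seed = seed)
  surface <- tidyr::expand_grid(sigma = sort(sigma_grid), ao = sort(ao_grid))
  correct <- matrix(0, nrow(surface), 1)
  for (sg in unique(surface$sigma)) {
    k_all <- compute_kernel(x, sigma = sg, kernel = kernel)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      cen <- center_kernel_train(k_all[tr, tr, drop = FALSE])
      ktec <- center_kernel_test(k_all[!tr, tr, drop = FALSE], cen$stats)
      for (ao in unique(surface$ao)) {
        core <- fit_kopls_kernel(cen$kc, y[tr], ao)
        yhat <- predict_kopls_kernel(core, ktec)$response
        row <- which(surface$sigma == sg & surface$ao == ao)
        correct[row] <- correct[row] + sum((yhat >= 0.5) == (y[!tr] == 1L))
      }
    }
  }
  surface$accv <- drop(correct) / length(y)
  best <- surface[order(-surface$accv, surface$ao, surface$sigma), ][1, ]
  structure(
    list(surface = surface, best_sigma = best$sigma, best_ao = best$ao,
         n_folds = n_folds, kernel = kernel,
         best_accv = best$accv),
    class = "kopls_tune"
  )
}

#' @export
print.kopls <- function(x, ...) {
  cat(sprintf(
    "Kernel-OPLS model (%s kernel%s), 1 predictive + %d orthogonal component(s)\n",
    x$kernel,
    if (x$kernel == "gaussian") sprintf(", sigma = %.4g", x$sigma) else "",
    x$core$ao
  ))
  cat(sprintf("  n = %d, R2X = %.3f, R2Y = %.3f\n",
              length(x$y), x$core$r2x, x$core$r2y))
  invisible(x)
}

#' @export
print.kopls_tune <- function(x, ...) {
  cat(sprintf("ACCV grid search: best sigma = %.4g, Ao = %d (ACCV = %.3f)\n",
              x$best_sigma, x$best_ao, x$best_accv))
  invisible(x)
}

#' Tidy a kernel-OPLS fit into its training scores
#'
#' @param x A `kopls` object.
#' @param ... Unused.
#' @return Tibble with one row per training sample: `sample`, `label`,
#'   fitted response, predictive score `t_p` and orthogonal scores `t_o*`.
#' @export
tidy.kopls <- function(x, ...) {
  out <- tibble::tibble(
    sample = seq_along(x$y),
    label = x$y,
    .fitted = x$fitted,
    t_p = x$core$t_p
  )
  if (x$core$ao > 0) {
    sc <- x$core$scores_ortho
    colnames(sc) <- paste0("t_o", seq_len(ncol(sc)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(sc))
  }
  out
}

#' One-row model summary of a kernel-OPLS fit
#'
#' @param x A `kopls` object.
#' @param ... Unused.
#' @return Tibble with `sigma`, `ao`, `r2x`, `r2y`, `n`.
#' @export
glance.kopls <- function(x, ...) {
  tibble::tibble(
    sigma = if (is.null(x$sigma)) NA_real_ else x$sigma,
    ao = x$core$ao,
    r2x = x$core$r2x,
    r2y = x$core$r2y,
    n = length(x$y)
  )
}
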