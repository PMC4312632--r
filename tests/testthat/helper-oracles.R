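# Independent reference implementations used as test oracles. These stay
# deliberately naive (loops, enumeration, primal-space algebra) and never
# call the package's kernel-space code paths.

# Primal single-response orthogonal PLS (NIPALS form): weights from the
# original X, per-component orthogonal deflation, final predictive score.
oracle_primal_opls <- function(x, y, ao, x_new) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  ym <- mean(y)
  yc <- y - ym
  w <- drop(crossprod(xc, yc))
  w <- w / sqrt(sum(w^2))
  wo_list <- list()
  po_list <- list()
  xi <- xc
  for (i in seq_len(ao)) {
    t <- drop(xi %*% w)
    p <- drop(crossprod(xi, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    wo <- wo / sqrt(sum(wo^2))
    to <- drop(xi %*% wo)
    po <- drop(crossprod(xi, to)) / sum(to^2)
    xi <- xi - tcrossprod(to, po)
    wo_list[[i]] <- wo
    po_list[[i]] <- po
  }
  t <- drop(xi %*% w)
  cc <- sum(yc * t) / sum(t^2)
  xn <- sweep(as.matrix(x_new), 2, mu)
  for (i in seq_len(ao)) {
    to_n <- drop(xn %*% wo_list[[i]])
    xn <- xn - tcrossprod(to_n, po_list[[i]])
  }
  list(
    fitted = cc * t + ym,
    pred = cc * drop(xn %*% w) + ym,
    r2y = 1 - sum((yc - cc * t)^2) / sum(yc^2)
  )
}

# Brute-force binomial upper tail: direct summation of the individual
# terms, smallest first, via log-space binomial coefficients.
oracle_binom_tail <- function(x, n, m, v) {
  p <- m / v
  i <- x:n
  terms <- exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p))
  sum(sort(terms))
}

# Brute-force AUC: concordant-pair counting with half-credit ties.
oracle_auc_pairs <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney P by enumerating every group assignment and
# counting pairwise wins (independent of the package's rank-sum route).
oracle_mw_exact <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  nn <- length(pool)
  u_of <- function(idx) {
    g1 <- pool[idx]
    g0 <- pool[-idx]
    total <- 0
    for (p in g1) for (q in g0) total <- total + (p > q) + 0.5 * (p == q)
    total
  }
  u_obs <- u_of(seq_len(n1))
  e_u <- n1 * (nn - n1) / 2
  sets <- utils::combn(nn, n1)
  u_all <- apply(sets, 2, u_of)
  mean(abs(u_all - e_u) >= abs(u_obs - e_u) - 1e-9)
}

# Drop the provenance attributes a SMOTE matrix carries, leaving the bare
# numeric matrix for value comparisons.
strip_smote_attrs <- function(m) {
  attr(m, "parent") <- NULL
  attr(m, "neighbor") <- NULL
  attr(m, "u") <- NULL
  dimnames(m) <- NULL
  m
}

# Small synthetic cohort shared by several tests.
small_cohort <- function(seed = 42, n0 = 40, n1 = 16, v = 20,
                         k = 2, effect = 3) {
  generate_cohort(synthetic_spec(
    n_class0 = n0, n_class1 = n1, n_features = v, n_informative = k,
    log2_effect = effect, seed = seed
  ))
}
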