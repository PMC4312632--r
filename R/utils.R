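#' @keywords internal
#' @useDynLib koplstrat, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Derive a reproducible per-stage seed from a master seed. Kept below
# .Machine$integer.max so it is always a valid `set.seed()` argument.
derive_seed <- function(master, stage, i = 0L) {
  as.integer((as.double(master) + 104729 * stage + 7919 * i) %% 2147483647)
}

# Run `expr` under a temporary RNG seed (no-op when seed is NULL).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    rlang::abort(sprintf(
      "`%s` must be a single finite number %s %s, got %s",
      name, if (strict) ">" else ">=", format(lower),
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= lower
  if (!ok) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d", name, lower))
  }
  invisible(as.integer(x))
}

assert_binary_labels <- function(y, name = "y") {
  if (!all(y %in% c(0, 1))) {
    rlang::abort(sprintf("`%s` must be coded 0/1", name))
  }
  invisible(as.integer(y))
}

# Stratified fold assignment: within each class, shuffle then deal the
# samples round-robin over folds. Every fold must see both classes.
make_stratified_folds <- function(y, n_folds, seed = NULL) {
  y <- assert_binary_labels(y)
  n_folds <- assert_count(n_folds, "n_folds", lower = 2L)
  folds <- integer(length(y))
  with_seed_if(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  tab <- table(factor(folds, levels = seq_len(n_folds)), y)
  if (any(tab == 0)) {
    rlang::abort(paste0(
      "some cross-validation folds contain a single class; ",
      "use fewer folds than the minority-class count"
    ))
  }
  folds
}

# Stratified half split: returns indices of the training half.
stratified_half_split <- function(y, seed = NULL, prop = 0.5) {
  y <- assert_binary_labels(y)
  with_seed_if(seed, {
    unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, max(1L, round(prop * length(idx))))
    }), use.names = FALSE)
  })
}
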