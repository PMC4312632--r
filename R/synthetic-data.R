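#' Specification of a synthetic two-class metabolomics cohort
#'
#' Describes an imbalanced serum-metabolomics cohort with planted group
#' effects. The defaults mirror the study conditions the package targets:
#' 238 majority-class (deficiency-like) and 57 minority-class (excess-like)
#' samples over 135 annotated features, four of which carry a true
#' up-regulation in the minority class, plus one near-constant
#' internal-standard feature (counted inside `n_features`).
#'
#' Intensities follow a feature-specific log-normal model: the base-10-ish
#' abundance spread comes from feature log-means drawn once per cohort, and
#' multiplicative log-normal noise with coefficient of variation `cv_noise`
#' is applied per observation. Planted effects multiply minority-class
#' intensities by `2^log2_effect` (direction +1), applied on the log scale so
#' intensities stay strictly positive.
#'
#' @param n_class0 Majority-class (deficiency) sample count.
#' @param n_class1 Minority-class (excess) sample count.
#' @param n_features Total feature count, internal standard included when
#'   `include_internal_standard` is `TRUE`.
#' @param n_informative Number of features with a planted effect.
#' @param log2_effect Planted shift, in log2 intensity units.
#' @param cv_noise Coefficient of variation of the multiplicative noise.
#' @param include_internal_standard Add one near-constant feature at the
#'   internal standard's coordinates (rt 1.00 min, m/z 200.0473)?
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_class0 = 238, n_class1 = 57, n_features = 135,
                           n_informative = 4, log2_effect = 2,
                           cv_noise = 1, include_internal_standard = TRUE,
                           seed = 1) {
  n_class0 <- assert_count(n_class0, "n_class0")
  n_class1 <- assert_count(n_class1, "n_class1")
  n_features <- assert_count(n_features, "n_features")
  n_informative <- assert_count(n_informative, "n_informative", lower = 0L)
  assert_scalar_number(log2_effect, "log2_effect")
  assert_scalar_number(cv_noise, "cv_noise", lower = 0, strict = TRUE)
  n_free <- n_features - as.integer(include_internal_standard)
  if (n_informative > n_free) {
    rlang::abort("`n_informative` exceeds the number of available features")
  }
  structure(
    list(
      n_class0 = n_class0, n_class1 = n_class1, n_features = n_features,
      n_informative = n_informative, log2_effect = log2_effect,
      cv_noise = cv_noise,
      include_internal_standard = isTRUE(include_internal_standard),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Internal-standard coordinates: [M+H]+ of L-chlorophenylalanine.
IS_MZ <- 200.0473
IS_RT <- 1.00

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param direction Per-informative-feature effect sign (+1 = higher in the
#'   minority class); recycled. Default all +1.
#' @return A list with elements `table` (a [peak_table()] carrying labels:
#'   first `n_class0` samples labelled 0, then `n_class1` labelled 1) and
#'   `truth` (tibble `feature_id`, `direction` for the planted features).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_class0 = 20, n_class1 = 8,
#'                                          n_features = 12, seed = 7))
#' dim(peak_intensities(cohort$table))
#' cohort$truth
generate_cohort <- function(spec, direction = 1L) {
  if (!inherits(spec, "synthetic_spec")) {
    rlang::abort("`spec` must be created with synthetic_spec()")
  }
  n <- spec$n_class0 + spec$n_class1
  v <- spec$n_features
  label <- rep(c(0L, 1L), c(spec$n_class0, spec$n_class1))
  sdlog <- sqrt(log1p(spec$cv_noise^2))
  withr::with_seed(spec$seed, {
    rt <- stats::runif(v, 0.5, 9.5)
    mz <- stats::runif(v, 100, 800)
    mu <- stats::rnorm(v, mean = log(1e4), sd = 1)
    is_idx <- integer(0)
    if (spec$include_internal_standard) {
      is_idx <- v
      rt[v] <- IS_RT
      mz[v] <- IS_MZ
      mu[v] <- log(5e4)
    }
    informative <- sort(sample(setdiff(seq_len(v), is_idx),
                               spec$n_informative))
    dir_vec <- rep_len(as.integer(direction), spec$n_informative)
    if (!all(dir_vec %in% c(-1L, 1L))) {
      rlang::abort("`direction` entries must be +1 or -1")
    }
    log_x <- matrix(stats::rnorm(n * v, sd = sdlog), n, v)
    if (spec$include_internal_standard) {
      # near-constant spiked standard: 2% CV irrespective of cv_noise
      log_x[, v] <- stats::rnorm(n, sd = sqrt(log1p(0.02^2)))
    }
    log_x <- sweep(log_x, 2, mu, "+")
    if (spec$n_informative > 0) {
      shift <- spec$log2_effect * log(2) * dir_vec
      log_x[label == 1L, informative] <-
        sweep(log_x[label == 1L, informative, drop = FALSE], 2, shift, "+")
    }
  })
  feature_id <- sprintf("M%03d", seq_len(v))
  if (spec$include_internal_standard) feature_id[v] <- "IS"
  table <- peak_table(
    exp(log_x),
    tibble::tibble(feature_id = feature_id, rt_min = rt, mz = mz),
    sample_id = sprintf("S%03d", seq_len(n)),
    label = label
  )
  list(
    table = table,
    truth = tibble::tibble(
      feature_id = feature_id[informative],
      direction = dir_vec
    )
  )
}

#' Generate a synthetic clinical covariate table
#'
#' Fixture for the clinical-characteristics summary: continuous covariates
#' are drawn normally with per-group means/SDs, binary covariates as
#' Bernoulli with per-group proportions. Defaults emulate an elderly type-2
#' diabetes cohort in which the deficiency (group 0) stratum is older and
#' heavier than the excess (group 1) stratum.
#'
#' @param n_subjects Number of subjects.
#' @param group_labels 0/1 vector of length `n_subjects`.
#' @param seed RNG seed.
#' @param continuous Named list; each element `c(mean0, sd0, mean1, sd1)`.
#' @param binary Named list; each element `c(p0, p1)` of per-group
#'   proportions.
#' @return Tibble with `sample_id`, `group`, and one column per covariate
#'   (binary covariates coded 0/1).
#' @export
generate_clinical_table <- function(
    n_subjects, group_labels, seed = 1,
    continuous = list(
      age = c(71.55, 8.50, 67.11, 9.49),
      bmi = c(25.46, 2.98, 24.57, 2.44),
      sbp = c(138.49, 14.73, 136.53, 14.40),
      dbp = c(78.10, 9.43, 79.72, 9.62)
    ),
    binary = list(
      obesity = c(0.534, 0.456),
      fatty_liver = c(0.769, 0.667),
      hypertension = c(0.924, 0.877)
    )) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  if (length(group_labels) != n_subjects) {
    rlang::abort("`group_labels` length must equal `n_subjects`")
  }
  g <- assert_binary_labels(group_labels, "group_labels")
  out <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_subjects)),
    group = g
  )
  withr::with_seed(as.integer(seed), {
    for (nm in names(continuous)) {
      par <- continuous[[nm]]
      out[[nm]] <- stats::rnorm(
        n_subjects,
        mean = ifelse(g == 0L, par[1], par[3]),
        sd = ifelse(g == 0L, par[2], par[4])
      )
    }
    for (nm in names(binary)) {
      par <- binary[[nm]]
      out[[nm]] <- stats::rbinom(n_subjects, 1L, ifelse(g == 0L, par[1], par[2]))
    }
  })
  out
}
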