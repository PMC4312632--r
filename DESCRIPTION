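Package: koplstrat
Title: Kernel-OPLS Stratification of Imbalanced Metabolomics Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies serum metabolomics profiles into two clinical strata
    from an imbalanced peak-intensity table. Provides total-sum normalization
    of LC-MS peak areas with internal-standard removal, SMOTE oversampling of
    the minority class, genetic-algorithm wrapper feature selection driven by
    a kernel-OPLS balanced-prediction-error fitness, kernel-OPLS
    classification with cross-validated kernel-width and orthogonal-component
    selection, a binomial selection-frequency test combined with Wilcoxon
    rank-sum validation for calling differential metabolites, and clinical
    cohort summary tables. A synthetic-cohort generator with planted effects
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    pROC,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
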