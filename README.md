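# koplstrat

Kernel-OPLS stratification of imbalanced metabolomics cohorts.

`koplstrat` implements a complete biomarker-discovery pipeline for the
setting where serum LC-MS peak-intensity profiles must separate two
clinical strata of very unequal size — the motivating cohort is a type-2
diabetes population split into a majority *deficiency* and a minority
*excess* traditional-Chinese-medicine syndrome (238 vs 57 subjects, ~135
annotated metabolites). Routine biochemistry does not distinguish the
strata; the metabolome does.

The pipeline:

1. **Preprocessing** — removal of the spiked internal standard's ion peaks,
   then total-sum normalization (each sample divided by its summed
   intensity).
2. **SMOTE** — synthetic minority oversampling `x + u (x_nn − x)` to full
   class balance, with the neighbour parameter *n* optimizable under the
   same wrapper objective used downstream.
3. **GA wrapper selection** — binary feature masks evolved by a simple
   genetic algorithm (population 30, initial selection ratio 0.1,
   single-point crossover 0.7) under a kernel-OPLS balanced-prediction-error
   fitness, repeated in independent runs to accumulate per-feature
   selection counts.
4. **Kernel-OPLS classification** — Gaussian-kernel orthogonal projections
   to latent structures with one predictive and `Ao` Y-orthogonal
   components; `σ` and `Ao` tuned by cross-validated classification
   accuracy (ACCV); performance reported as ACCV, R²X, R²Y, Q²Y, AUC with a
   DeLong 95% CI, sensitivity, specificity, total and balanced accuracy.
5. **Dual-criterion calling** — a feature is a differential metabolite when
   the binomial selection-frequency tail probability
   `P(x) = Σ_{i=x}^{n} C(n,i) (m/v)^i (1−m/v)^{n−i}` over the GA runs falls
   below 0.001 **and** a Wilcoxon rank-sum test confirms the univariate
   difference at P < 0.05.

Because no cohort data are deposited, a first-class synthetic-data module
(`generate_cohort()`) emulates the study conditions — log-normal
intensities, a 238/57 imbalance over 135 features, an internal-standard
feature, and four planted up-regulated metabolites — so the entire pipeline
is testable end to end with known ground truth.

## Worked example

```r
library(koplstrat)

cohort <- generate_cohort(synthetic_spec(seed = 1))   # 295 x 135, 4 planted
config <- pipeline_config(
  smote_n = 3,
  ga = ga_config(n_generations = 40, n_runs = 20, seed = 1),
  sigma_grid = c(0.5, 1, 2.5, 5), ao_grid = 0:2, n_folds = 5,
  seed = 1
)
result <- run_stratification(cohort$table, config)

dplyr::filter(tidy(result), passes)
#> # A tibble: 4 × 7
#>   feature_id count n_runs     p_ga p_wilcoxon direction passes
#>   <chr>      <dbl>  <int>    <dbl>      <dbl>     <int> <lgl>
#> 1 M025          10     20 5.29e- 4   4.43e-15         1 TRUE
#> 2 M041          18     20 1.02e-12   2.07e-18         1 TRUE
#> 3 M066          10     20 5.29e- 4   2.51e-16         1 TRUE
#> 4 M121          19     20 2.08e-14   8.77e-18         1 TRUE
```

The four called features are exactly the four planted metabolites, all
higher in the minority (excess-like) class. `glance(result)` returns the
model report — one protocol-faithful resubstitution row and one honest
held-out row; in the run above the resubstitution model reached AUC 0.968
(95% CI 0.949–0.987, balanced accuracy 0.883, ACCV 0.857, Q²Y 0.563) at
the tuned `(σ, Ao)`.
`autoplot(result$model)` draws the predictive-vs-orthogonal score plot,
`autoplot(result$counts)` the GA selection-frequency profile.

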