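# tcpca — tensorized contrastive PCA for longitudinal clinical cohorts

Longitudinal dementia cohorts record each subject as a visits × features
matrix, and the dominant variance in those matrices is usually not the
disease: it is natural aging, the smooth drift that cognitively normal
elderly show in the same imaging and cognitive measures. `tcpca` builds
representations that subtract an aging background on **both** axes of the
subject × visit × feature tensor, for researchers doing progression
prediction and clinical subtype discovery on cohort exports (one row per
subject-visit).

## The model

Given a target (disease) cohort of centered `p × k` subject matrices `S_i`
and a background (never-diseased) cohort, the package forms per-axis cohort
covariances

- feature axis (`k × k`): `C = (1/N) Σᵢ (Sᵢ − S̄)ᵀ(Sᵢ − S̄)`
- time axis (`p × p`): `C = (1/N) Σᵢ (Sᵢ − S̄)(Sᵢ − S̄)ᵀ`

and takes the leading eigenvectors of the contrastive combination

```
C_target − α · C_background ,        one α ≥ 0 per axis,
```

directions that maximize `vᵀ(C_target − α C_background) v` — variance
enriched in the disease cohort relative to aging. Subjects are then projected
bilinearly, `Sᵢᶜ = M_timeᵀ Sᵢ M_feature`, and the flattened `Sᵢᶜ` feeds
classifiers and clustering. At `α = 0` this is ordinary two-sided PCA; the
`feature_only` / `time_only` modes are the two single-axis ablations.

Around that core the package ships the full working pipeline:

- cohort ingestion, visit-grid alignment, nearest-subject imputation,
  pooled per-cell standardization (`read_cohort()`, `align_time_grid()`,
  `impute_missing()`, `standardize_cohorts()`);
- comparator representations: raw flattening, seven-statistic time-series
  summaries, 2DPCA, and five kernel-PCA variants (`represent()`);
- a fireworks-algorithm optimizer for `(α_feature, α_time)` in log space
  (`fwa_optimize()`, `tune_alphas()`);
- repeated stratified 3-fold evaluation of 3-class progression labels
  (better / worse / unchanged at a 1-, 3- or 5-year horizon) with
  macro-averaged metrics and one-sided paired t-tests (`evaluate()`,
  `comparison_grid()`, `paired_model_test()`);
- hierarchical-clustering subtype discovery with silhouette model selection
  and before/after-clustering comparison (`fit_subtypes()`,
  `per_cluster_evaluation()`);
- random-forest Gini importance in the literal unweighted node-difference
  form, with per-visit profiles (`gini_importance_of()`,
  `longitudinal_importance()`, `representative_features()`);
- a seed-deterministic synthetic-cohort generator with planted aging and
  disease axes, subtypes, and labels (`generate_cohorts()`).

Results are tibble-first (`tidy()`, `glance()`, `autoplot()` methods
throughout), and a thin CLI over the same functions lives at
`inst/cli/tcpca.R` (subcommands `simulate`, `fit`, `transform`, `represent`,
`tune`, `evaluate`, `subtype`, `importance`).

## Worked example

```r
library(tcpca)

sim <- generate_cohorts(synthetic_spec(seed = 42))   # 400/200 subjects, 8 visits, 60 features
fit <- fit_tcpca(sim$pair, alpha_feature = 50, alpha_time = 50)
fit
#> <tcpca_fit> mode = full
#>   feature basis: 60 x 1 (alpha = 50)
#>   time basis:    8 x 1 (alpha = 50)

abs(sum(fit$basis_feature[, 1] * sim$truth$u_dis[, 1]))
#> [1] 0.965      # the top contrastive direction is the planted disease axis

rep <- predict(fit, sim$pair$target)
ft  <- feature_table(rep$flat, sim$pair$target$subject_ids, "TcPCA")
evaluate(ft, sim$truth$labels, classifier_spec("knn"), n_runs = 5, seed = 1)
#> <eval_entry> knn on TcPCA: 5 runs x 3 folds
#>   metric  mean     sd
#> 1 acc    0.859 0.0192
#> 2 f1     0.438 0.0404
#> 3 recall 0.434 0.0478

mod <- fit_subtypes(rep, k_range = 2:8)
mod
#> <subtype_model> K = 4 (ward.D2 linkage), sizes: 103, 97, 100, 100
#>   mean silhouette at K: 0.782
mclust::adjustedRandIndex(mod$assignments, sim$truth$subtype)
#> [1] 0.98
```

Read as: at strong contrast the leading feature direction aligns with the
planted disease axis (|cosine| 0.965) instead of the dominant aging axis;
3-fold CV accuracy on the heavily imbalanced 3-class labels is 0.86 (macro
recall is much lower — the "better" class is ~3.5% of subjects); silhouette
selection recovers the four planted subtypes nearly perfectly (adjusted Rand
0.98). The methods vignette (`vignettes/tcpca-methods.Rmd`) documents the
model, the conventions, and what these synthetic checks do and do not show.

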