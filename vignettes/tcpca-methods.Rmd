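---
title: "Contrasting disease progression against natural aging in longitudinal clinical tensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting disease progression against natural aging in longitudinal clinical tensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcpca)
```

## The problem

Longitudinal clinical studies of dementia record each subject repeatedly on a
fixed visit schedule, producing one matrix per subject: `p` visits by `k`
clinical features (imaging volumes, cognitive scores, CSF biomarkers, and so
on). Two sources of variance are entangled in such data. Cognitively normal
elderly change too — "natural aging" drives smooth, monotone drift in many of
the same features that dementia affects — and this shared drift usually
dominates the spectrum of any plain variance decomposition. A representation
built for progression prediction or subtype discovery should emphasize the
variance that is specific to the *disease* cohort, not the variance every
aging brain shows.

`tcpca` implements tensorized contrastive PCA (T-cPCA) for exactly this
setting: contrastive PCA applied separately to the feature axis and the time
axis of a subject × visit × feature tensor, using a background cohort of
never-diseased subjects as the model of natural aging.

## The model

Write `S_i` for the `p × k` matrix of target-cohort subject `i`, centered by
the cohort mean matrix, and likewise for the background cohort. Per axis the
package forms cohort covariances

* feature axis: `C = (1/N) Σ_i (S_i − S̄)ᵀ (S_i − S̄)` (`k × k`),
* time axis: `C = (1/N) Σ_i (S_i − S̄)(S_i − S̄)ᵀ` (`p × p`),

and the contrastive combination `C_target − α · C_background`, one trade-off
`α ≥ 0` per axis. Its leading eigenvectors maximize
`vᵀ(C_target − α C_background)v`: directions of variance *enriched* in the
disease cohort relative to aging. With basis matrices `M_time` (`p × m_time`)
and `M_feature` (`k × m_feature`), every subject is projected bilinearly,

```
S_i^change = M_timeᵀ S_i M_feature ,
```

an `m_time × m_feature` matrix whose row-major flattening feeds the
downstream classifiers and the clustering. At `α = 0` on both axes the method
reduces to ordinary two-sided PCA of the target cohort; the two ablations
keep one axis untouched (identity basis).

Three modelling conventions deserve a note because the underlying notation is
ambiguous in the field:

* **Centering.** Each cohort is centered by its own mean tensor (the mean
  over subjects). Centering by individual subjects would null the covariances
  entirely; a shared pooled mean would mix disease prevalence into both
  covariances.
* **Indefiniteness.** `C_target − α C_background` is generally indefinite.
  Directions are ranked by *algebraic* eigenvalue, matching the variance-
  contrast argmax; at large `α` the whole spectrum may be negative, in which
  case the leading (least-negative) direction is still well defined and
  automatic rank selection falls back to a single component.
* **No re-centering at projection time.** The bilinear map is applied to the
  (standardized) `S_i` as-is; centering and scale live in the stored scaling
  record so held-out subjects are transformed identically.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha_feature`, `alpha_time` | background-suppression strength per axis (unitless) | 1; tuned by `tune_alphas()` | 0 = plain PCA; larger values subtract aging harder at the cost of amplifying background sampling noise |
| `m_feature`, `m_time` | retained components per axis | smallest ranks capturing 90% of the positive contrastive eigenvalue mass | the positive part of the spectrum is the target-enriched variance; 0.9 is the usual scree-style cutoff |
| `n_neighbors` | neighbours for nearest-subject imputation | 5 | small enough to stay local, large enough to average measurement noise |
| visit grid | labels and month offsets | 8 semiannual visits, months 0–42 | the cohort layout the package's simulations emulate; fully configurable |
| silhouette `k_range` | candidate cluster counts | 2–10 | covers the plausible subtype counts reported for dementia cohorts |
| Gini threshold | representative-feature cutoff | 0.02 (strictly greater) | the conventional cutoff on normalized importance |

## Preprocessing

`read_cohort()` ingests a long table (one row per subject-visit) and is
order-invariant; `align_time_grid()` reindexes onto the configured grid and
drops subjects observed at fewer than half the visits (configurable);
`impute_missing()` fills each unobserved cell with the mean of that cell over
the nearest subjects, where distance is the root *mean* squared difference
over jointly observed cells — the mean, not the sum, so sparsely overlapping
pairs are not spuriously close. Last-observation-carried-forward is available
as an alternative. `standardize_cohorts()` z-scores per (visit, feature) cell
with moments pooled over both cohorts, so the contrastive subtraction
compares like scales; zero-variance cells are set to 0 and flagged, and the
scaling record reproduces the transformation on held-out data exactly.

Whether to standardize at all is a genuine modelling choice. For real
clinical exports with incommensurate units it is essentially mandatory. For
data already on a common scale it is not neutral: dividing each cell by its
own standard deviation deflates exactly the cells where a planted signal
loads, which warps signal axes at large `α`. The package's synthetic checks
therefore run on the generator's native scale, and the same consideration
applies to any real dataset whose features share units.

## Hyperparameter search: the fireworks algorithm

`(α_feature, α_time)` is tuned by a fireworks algorithm — a population
optimizer in which each candidate ("firework") explodes into displacement
sparks, with better candidates earning more sparks on smaller radii and worse
ones fewer sparks on larger radii, plus a few Gaussian-mutation sparks;
out-of-box sparks are mapped back by modular arithmetic and the next
generation keeps the elite best plus survivors drawn by distance-weighted
roulette. Two numerical choices matter:

* the raw inverse-fitness amplitude rule assigns the best firework a
  near-zero radius, which stalls refinement; the implementation enforces a
  lower amplitude bound that decays linearly with the spent evaluation
  budget (5% of the box down to 0.01%), the standard cure;
* the search runs in `log10(α)` space over `[10⁻², 10³]²` by default, since
  the useful scale of `α` is multiplicative.

The tuning objective is mean stratified 3-fold cross-validated accuracy
(optionally macro-F1) of a configurable classifier on the T-cPCA
representation, with the folds drawn once per run so every candidate is
scored on identical splits. Runs are reproducible: all randomness descends
deterministically from the configured seed.

## Evaluation protocol

Progression labels are three-class: diagnosis ordinal (CN < MCI < dementia)
compared between the end of the observation window and a 1-, 3- or 5-year
horizon — better (+1), worse (−1), unchanged (0). Evaluation uses repeated
seeded stratified 3-fold cross-validation (10 runs by default); recall and F1
are macro-averaged over the classes present in the test fold (the label
distribution is heavily imbalanced, and macro averaging keeps the rare
"better" class visible). Model comparisons are one-sided paired t-tests on
fold-level scores sharing identical (run, fold) splits, declared significant
only when `p ≤ 0.01` *and* `T > 2`; constant difference vectors bypass the
t-test (flagged degenerate). The classifiers are a single-hidden-layer
perceptron, a random forest, and k-nearest neighbours with recorded
hyperparameters. One practical cap: the perceptron is trained by
quasi-Newton optimization whose workspace grows with the square of the
weight count, so the hidden layer shrinks automatically on very wide inputs
to respect a total-weight budget (default 5000) — relevant only for the raw
flattened representation, whose width is `p·k`.

## Subtype discovery

Hierarchical clustering (Ward linkage on Euclidean distances of the flattened
representation; complete/average available) is cut at every K in the search
range and the mean silhouette width selects K, ties to the smaller K. The
before/after comparison then reruns the same classifier with identical
hyperparameters pooled versus within each cluster, aggregating per-cluster
metrics weighted by cluster size; clusters too small for the folds, or with a
single label class, are merged into the nearest centroid's cluster first.
With a single cluster the two phases coincide exactly, which is also how the
machinery is tested.

## Feature importance

Random-forest Gini importance follows the unweighted node-difference form:
for every split on feature `x_j`, the contribution is
`GI_parent − GI_left − GI_right` with `GI = 1 − Σ_c p_c²`, summed over the
feature's occurrences within a tree and over trees, then normalized to sum
to 1. This differs from the common sample-weighted impurity decrease, which
is available behind `weighted = TRUE`. Two consequences of the unweighted
form are handled explicitly: a split can net out negative (both children
nearly as impure as the parent), so per-feature totals are clamped at zero
before normalization; and the scores are comparable only within one fitted
forest. Forests are grown by `ranger` with recorded in-bag counts; per-node
class counts are reconstructed by routing the in-bag samples through the
recorded splits, and the implementation is verified against an independent
recursive traversal in the test suite. Per-visit profiles (`longitudinal_importance()`)
fit a fresh seeded forest on each visit slice, giving a `p × k` map of when
each feature matters.

## The synthetic generator

`generate_cohorts()` produces the structure the method assumes, with known
ground truth: a shared low-rank aging component (orthonormal feature
directions with smooth monotone time trends) in both cohorts; a target-only
disease component on feature directions orthogonal to aging, with a
late-onset ramp profile (flat to mid-span, then rising) — monotone drift
versus late divergence is precisely what makes the time-axis contrast
informative; planted subtypes as centroids in disease-score space (spacing in
units of within-subtype spread); three-class labels from a logistic latent
score thresholded at sample quantiles so the requested class mix is honored;
optional uniform missingness; and a single measurement-noise level shared by
both cohorts. Component scores are standardized in-sample, so the variance
shares (`σ²_age`, `σ²_dis`, noise as the remainder, summing to 1 per cell)
hold exactly by construction.

Defaults are the desk-scale study conditions used throughout the tests:
400 target and 200 background subjects, 8 visits, 60 features,
`σ²_age = 0.6`, `σ²_dis = 0.15`, four subtypes at 10-sigma separation, and
the 1-year label mix of roughly 3.5% better / 10% worse / 86% unchanged.
`default_study_scale_spec()` switches to the full cohort sizes (1909/884)
and exposes the full 872-feature width. What the generator deliberately does
*not* emulate: real marginal distributions, units and modality blocks,
informative (non-random) missingness, visit-schedule jitter, and
label noise from diagnostic disagreement. Passing the planted-recovery tests
therefore demonstrates that the machinery isolates a disease subspace under
the model's own assumptions — not that those assumptions hold for any
particular clinical export.

## Numerical conventions

* Covariances are symmetrized as `(C + Cᵀ)/2` before eigendecomposition.
* Eigenvector signs are fixed (largest-magnitude entry positive, first such
  index on ties) so results are platform-reproducible; exact eigenvalue ties
  keep the solver's index order.
* All derived random streams (fold draws, classifier initialization, forest
  seeds) come from a single master seed through a deterministic hash, and
  evaluation reports are byte-identical across runs with the same seed. The
  random-forest path also pins the R RNG, which the forest backend consults
  for prediction vote ties.
* Degenerate cases are contracts, not accidents: zero-variance cells → 0
  with a flag; all-negative contrastive spectra → rank-1 fallback (strict
  error in `select_ranks()`); constant paired differences → degenerate
  t-test record; single-cluster models → before ≡ after.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated data at
the desk-scale defaults above (seconds to a couple of minutes per block),
plus one full-width smoke run at 400/200 subjects × 8 visits × 872 features
with a reduced tuning budget. Ten-run cross-validation appears where the
protocol itself is under test; elsewhere two to five runs give the same
decisions faster.

## Known limitations

* The contrast amplifies background *sampling* noise linearly in `α`: with a
  finite background cohort, very large `α` trades aging suppression for
  noise chasing. Tuning `α` on a downstream objective, not maximizing it, is
  the intended use.
* Nearest-subject imputation loops over missing cells in R; it is fine at
  thousands of missing cells, not millions.
* The ablation naming follows the convention that the feature-only variant
  is the zeroth ablation and the time-only variant the first.
* Kernel PCA components with nonpositive eigenvalues (indefinite sigmoid
  kernels) are dropped with a warning rather than imputed.
* `class::knn` breaks distance ties randomly; with the seeded wrapper this
  is reproducible but still a tie-break, visible only in degenerate
  duplicated-point data.
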