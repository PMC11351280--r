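Package: tcpca
Title: Tensorized Contrastive PCA for Longitudinal Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Representation learning for subject x visit x feature clinical
    tensors by contrastive principal component analysis applied jointly to the
    feature and time axes (T-cPCA): the variance structure of a background
    cohort (natural aging) is subtracted from a target (disease) cohort on both
    axes before bilinear projection. Includes cohort ingestion, visit-grid
    alignment, nearest-subject imputation and standardization; comparator
    representations (raw flattening, per-feature time-series summaries, 2DPCA,
    kernel PCA); a fireworks-algorithm optimizer for the contrast strengths;
    stratified cross-validated progression-prediction evaluation with paired
    t-tests; hierarchical-clustering subtype discovery with silhouette model
    selection; random-forest Gini feature importance with per-visit profiles;
    and a synthetic-cohort generator with planted aging and disease structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    class,
    cluster,
    dplyr,
    generics,
    ggplot2,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    kernlab,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
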