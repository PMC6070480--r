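Package: sccanet
Title: Sparse Canonical Correlation Analysis Linking Functional Connectomes
    to Psychiatric Symptoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for linking high-dimensional functional
    connectivity features to item-level psychiatric symptoms with sparse
    canonical correlation analysis (sCCA). Implements rank-1 penalized matrix
    decomposition with elastic-net constraints and deflation for multiple
    variates; median-absolute-deviation edge selection and covariate
    residualization; grid-search tuning of sparsity parameters on resampled
    subsets; permutation significance testing with clinical-loading variate
    matching and false discovery rate correction; bootstrap-style resampling
    for feature stability selection; within- and between-community loading
    summaries on the brain graph with label-permutation inference;
    cross-dimension common-edge overlap against a density-preserving null; and
    generalized additive models for age and sex effects on dimension scores.
    Includes a synthetic-cohort generator with planted canonical structure so
    the full pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
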