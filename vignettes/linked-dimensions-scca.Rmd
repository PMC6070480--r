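---
title: "Linking functional connectomes to symptom dimensions with sparse CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking functional connectomes to symptom dimensions with sparse CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccanet)
```

## The problem

Psychiatric symptoms rarely respect diagnostic category boundaries, and
functional connectivity differences associated with psychopathology are
spread across many weak edge-level effects rather than concentrated in a
single circuit. `sccanet` implements a multivariate pipeline that looks for
*linked dimensions*: sparse patterns of functional connectivity (edges
between parcellated brain regions) and sparse patterns of clinical symptom
items whose subject-level expressions are maximally correlated.

The two views are a subjects × features connectivity matrix
$X_{n \times p}$, built by vectorizing each subject's symmetric node × node
correlation matrix, and a subjects × items clinical matrix $Y_{n \times q}$
of ordinal screening responses.

## The model

Each canonical variate is a pair of loading vectors $(u, v)$ solving the
penalized matrix decomposition (PMD) problem

$$
\max_{u, v} \; u^{\top} X^{\top} Y v
\quad \text{s.t.} \quad
\lVert u \rVert_2^2 \le 1,\;
\lVert v \rVert_2^2 \le 1,\;
\lVert u \rVert_1 \le c_1,\;
\lVert v \rVert_1 \le c_2 .
$$

The joint $L^1$/$L^2$ constraints are an elastic net: the $L^2$ budgets are
fixed at 1, while $c_1, c_2$ control sparsity and are exposed as fractions
in $[0, 1]$ of the loosest useful bound, $c = \max(1, \text{frac}
\cdot \sqrt{\dim})$. A fraction of 1 makes the $L^1$ constraint inactive
(by Cauchy–Schwarz); a fraction of 0 collapses to a single feature.

`fit_component()` solves one rank-1 problem by alternating updates
$u \leftarrow \Pi(Z v; c_1)$, $v \leftarrow \Pi(Z^{\top} u; c_2)$ with
$Z = X^{\top} Y$, where $\Pi(a; c)$ soft-thresholds $a$ just enough that
the normalized result satisfies the $L^1$ bound. The threshold solves a
per-segment quadratic in closed form on the sorted $|a_i|$ knots (the
$L^1/L^2$ ratio is strictly decreasing in the threshold between knots); a
bisection fallback guards degenerate segments. Further variates come from
deflation, $Z_{k+1} = Z_k - d_k u_k v_k^{\top}$ with $d_k = u_k^{\top} Z_k
v_k$.

### Assumptions

* Linear linkage: each variate captures a linear combination of edges and a
  linear combination of items. No kernelized or nonlinear extension is
  provided.
* Sparsity: the interesting loading patterns involve a minority of edges
  and items. The stability-selection stage (below) presumes the solver
  operates in this sparse regime.
* Exchangeable subjects: permutation and resampling inference treat
  subjects as independent draws.

## Pipeline stages and their parameters

| Stage | Function | Key parameters (defaults) |
|---|---|---|
| Feature build | `vectorize_connectivity`, `filter_by_mad` | retained fraction (0.1) |
| Confound removal | `residualize` | covariate subset |
| Scaling | `standardize` | population-sd convention |
| Tuning | `grid_search` | step 0.1, 10 draws of 2/3 of subjects |
| Fit | `fit_scca` | `c1_frac`, `c2_frac` (0.5), K, tol 1e-6, 100 iter |
| Scree selection | `select_components` | above-mean covariance-explained |
| Significance | `permutation_test` | B (1000), per-variate mode |
| Stability | `stability_resample` | R (1000), 99% / 95% CIs |
| Graph summary | `module_label_permutation`, `common_edge_overlap` | B |
| Development | `dimension_scores`, `fit_age_sex_gam` | basis k = 10, REML |

Notes on individual choices:

* **Feature enumeration.** The upper triangle *including* the diagonal, in
  row-major order, so an $N$-node matrix yields $N(N+1)/2$ unique features
  (34,980 for a 264-node parcellation). Diagonal entries of a correlation
  matrix are constant and always fall to the bottom of the MAD ranking, so
  they never survive filtering; enumerating them keeps the printed feature
  count of the 264-node convention exact. The retained count is
  $\lfloor \text{fraction} \times p \rfloor$; the realized count is always
  reported rather than hard-coded, since published retained counts may
  reflect additional unstated filtering.
* **MAD.** `mad_raw` is the raw median of absolute deviations from the
  median (no normal-consistency constant), with midpoint medians at even
  lengths. Ties in the ranking break by feature order, making selection
  deterministic.
* **Residualization.** Per-column least squares on an intercept plus
  reference-coded covariates, applied before standardization. Edge weights
  enter as raw correlations; no Fisher z-transform is applied (the sCCA
  objective is invariant to monotone per-feature rescalings only through
  the standardization step, so the choice is recorded here).
* **Standardization.** Population (denominator-$n$) standard deviation;
  each column has mean 0 and sd 1. Whether the original analyses scaled
  columns before sCCA is not documented anywhere we could verify, so
  standardization defaults on and is a separate, skippable step.
* **Initialization and convergence.** $v_0$ is the leading right singular
  vector of $Z$ (deterministic); iteration stops when the largest absolute
  change in $(u, v)$ falls below `tol` = 1e-6 or after `max_iter` = 100
  alternations, whichever is first. The objective $u^{\top} Z v$ is
  non-decreasing across iterations; non-convergence is recorded in the
  model's convergence log.
* **Sign convention.** $d_k$ is made non-negative by flipping $u_k$; then
  $(u_k, v_k)$ are jointly flipped so the largest-magnitude clinical
  loading is positive (ties to the lowest item index). Joint flips change
  nothing statistical; the convention only stabilizes reporting.
* **Covariance explained.** Defined as $d_k / \sum_j d_j$ (fractions sum
  to 1); the squared alternative $d_k^2 / \sum_j d_j^2$ is available via
  `covariance_explained(model, method = "d2")`. No published formula
  exists for the scree statistic this mirrors, so the simpler definition
  is the default and is the one used by `select_components`, which keeps
  the variates lying strictly above the mean fraction (the "dashed line"
  rule on a scree plot).
* **Tuning.** The grid covers $\{0.1, \dots, 1.0\}^2$ by default; fraction
  0 is excluded as degenerate but can be included. The chosen cell
  maximizes the mean first-variate correlation over random two-thirds
  subsamples; ties prefer the sparser cell. Replication runs must supply
  frozen fractions — `run_config(role = "replication", c1_frac = "tune")`
  is a validation error.
* **Permutation test.** Rows of $Y$ are shuffled, the model is refitted
  with identical parameters and $K = \max(\text{selected})$ components,
  and permuted variates are matched back to the observed ones by greedy
  one-to-one assignment on $|\text{cor}(v^{\text{perm}}, v^{\text{obs}})|$
  (permutation can reorder variates and flip signs). The empirical p is
  the literal count of matched null correlations at or above the observed
  one divided by B; `add_one = TRUE` switches to $(\text{count}+1)/(B+1)$,
  recommended for small B. The published description compares nulls to
  "the average" observed correlation, which is ambiguous between
  per-variate and aggregate readings; the per-variate comparison is the
  default (it matches the way observed correlations are marked on null
  histograms) and `mode = "aggregate"` implements the other reading.
  q-values are Benjamini–Hochberg across the selected variates.
* **Stability resampling.** Each draw takes two-thirds of subjects without
  replacement and restores the sample size by redrawing the remaining
  third with replacement from those two-thirds — our reading of a
  bootstrap-like scheme whose published description does not pin down the
  final sample size. Percentile CIs: 99% for connectivity loadings, 95%
  for clinical loadings; a feature is stable when its CI excludes zero.
* **Variate matching.** Greedy by default; `method = "optimal"` performs
  exhaustive one-to-one assignment and is sensible for more than ~3
  variates, where greedy choices can cascade.
* **Module summaries.** Mean within-community loading
  $\sum_{i,j \in m} 2 W_{ij} / (|M|(|M|-1))$ and between-community loading
  $\sum_{i \in m, j \in n} W_{ij} / (|M||N|)$, computed on loading
  matrices rebuilt from stability-surviving features only. Label
  permutations preserve community sizes; the test statistic is the
  absolute mean loading (two-sided), since loadings carry sign. All
  communities enter computation — excluding small or unsorted communities
  is a visualization decision, not a statistical one.
* **Common-edge overlap.** "Preserving edge density" in the null is read
  as preserving each dimension's edge *count*; null edge sets are uniform
  over off-diagonal unordered pairs, and any edge ever appearing in a null
  intersection is eliminated. A degree-sequence-preserving null would be a
  natural extension but is not implemented. The overlap threshold equals
  the number of dimensions supplied.
* **Developmental GAMs.** Age and sex effects are modeled on dimension
  scores computed from data residualized for race and motion only, because
  scores from fully residualized data contain no age or sex variation by
  construction. The default recomputes the scores by refitting sCCA on the
  partially residualized matrices and matching variates back to the
  reference model; `mode = "project"` projects onto the reference loadings
  instead. The GAM is `score ~ sex + s(age, k = 10)` with REML smoothness
  selection via mgcv; the age-by-sex interaction, when requested, is a
  sex-specific smooth deviation tested in a separate model. FDR is applied
  across dimensions separately per effect family, and the basis size is a
  documented default, not a claim about the original analyses.

## The synthetic cohort generator

`generate_cohort()` plants known structure so every stage can be tested for
recovery:

* latent factors $t_k \sim N(0,1)$ per subject drive both views through
  unit-norm sparse loading vectors $u^*_k$ (over off-diagonal edges) and
  $v^*_k$ (over items), scaled by $\sigma_k$;
* edge pre-values get a baseline elevated inside communities (0.35 vs 0.10
  on the pre-squash scale) so block structure is visible, plus confound
  terms and $N(0, \text{noise\_sd}^2)$ noise, and are squashed into
  $(-1, 1)$ by tanh — a monotone map that preserves the planted rank
  structure while keeping values in the range of correlations;
* clinical latents are discretized at fixed equal-mass quantiles into
  `item_levels` ordinal levels;
* confounds (age, sex, race, motion) act on each view along fixed random
  unit directions scaled by configured effect sizes, applied to
  standardized covariate encodings;
* covariates emulate a developmental community cohort qualitatively: age
  uniform on 8–22 years, balanced sex, a 3-level ancestry-like category,
  log-normal in-scanner motion (mm).

Defaults mirror the discovery-scale design the package targets: 663
subjects, 264 nodes in 14 communities, 111 items, four latent dimensions
with decreasing effect scales (3, 2.5, 2, 1.5) and unit noise. The item
marginals, the tanh squash, and the dense random confound directions are
stand-ins chosen for simplicity, not claims of fidelity: real item
distributions are heavily skewed, real edge distributions are not tanh-
Gaussian, and real confounds act nonuniformly. Passing recovery tests on
these cohorts therefore demonstrates correctness of the estimation
machinery under the planted model, not performance on real cohorts.

A subtlety worth knowing: the tanh squash makes confound effects slightly
nonlinear in the covariates, so linear residualization leaves a small
nonlinear confound residue in the edge features. This is deliberate — real
confounds are not exactly linear either — but it means simulated "null"
features are not perfectly null when confound effects are large.

## Recovery scoring

`score_recovery()` aligns estimated variates to planted dimensions by
greedy one-to-one matching on the mean of the two per-view absolute loading
correlations, and reports per dimension the pair of sign-aligned
correlations plus their minimum as the headline `recovery`. Using the
minimum means a dimension counts as recovered only when *both* its
connectivity and its clinical pattern are found; a correlation over the
concatenated loading vector was rejected because the much shorter clinical
view dominates its null distribution.

## Numerical choices and degenerate inputs

* Threshold solution tolerance: exact on knot segments; bisection fallback
  stops at an interval of $10^{-10} \max_i |a_i|$.
* `l1_constrain` with $c = 1$ returns the signed unit vector at the
  largest $|a_i|$ (ties to the lowest index) rather than bisecting, which
  would collapse tied maxima to a zero vector.
* An all-zero cross-product matrix, a zero-variance column entering
  standardization, a rank-deficient residualization design, a singleton
  community in a within-loading, and mismatched subject counts are all
  hard errors naming the offending object.
* Stage seeds in `run_pipeline` derive deterministically from the master
  seed; every stochastic stage records its seed in the provenance file.

## What the checks actually run

The test suite exercises the solver against SVD and brute-force oracles on
30×20 problems, full-pipeline recovery on cohorts of 500 subjects with 300
edge features and 40 items over 10 seeds, permutation calibration with 200
replicates of independent 150-subject views at B = 200, stability
selection on 400-subject cohorts at R = 200 with loadings planted at 0.4,
the module-loading identities on every partition of an 8-node graph, and
GAM recovery at 300 subjects. These sizes are the package's reference
simulation conditions; the inferential defaults (B = R = 1000) are larger.

## Known limitations

* **Stability CIs are anticonservative outside the sparse regime.**
  Percentile CIs from overlapping resamples center on the full-sample
  statistic, not on the population value. When a penalty is loose enough
  that a null feature's loading is nonzero with a consistent sign in
  nearly every resample — always true for an unpenalized view — the CI
  excludes zero more often than the nominal error rate suggests. Grid
  search tuned on subsample correlation tends to choose loose clinical
  penalties, so stable-feature counts under tuned parameters should be
  read as descriptive, not as error-controlled discoveries.
* Greedy variate matching can mis-assign when several variates have
  similar clinical loadings; use `method = "optimal"` when in doubt.
* The covariance-explained scree rule is a heuristic; with K extracted
  components the mean fraction depends on K itself.
* The generator's ordinal items are equal-mass by construction; methods
  sensitive to item skew are not stress-tested here.
* Only linear confound removal is provided, and the PCA-based
  dimensionality-reduction alternative to MAD filtering is out of scope.
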