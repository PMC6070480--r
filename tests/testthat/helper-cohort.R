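# Shared fixtures: small synthetic cohorts and the standard preparation
# chain (vectorize -> MAD filter -> residualize -> standardize).

small_cohort <- function(seed = 1L, n = 80L, nodes = 12L, items = 10L,
                         K = 1L, sigma = 3, noise_sd = 1,
                         conn_support = 8L, clin_support = 4L, ...) {
  sizes <- rep(nodes %/% 3, 3)
  sizes[1] <- sizes[1] + nodes - sum(sizes)
  names(sizes) <- c("a", "b", "c")
  generate_cohort(cohort_config(
    n_subjects = n, n_nodes = nodes, community_sizes = sizes,
    n_items = items, n_latent = K, conn_support_sizes = conn_support,
    clin_support_sizes = clin_support,
    effect_scales = if (K > 0) sigma else numeric(0),
    noise_sd = noise_sd, seed = seed, ...))
}

prep_xy <- function(cohort, fraction = 1.0) {
  fm <- filter_by_mad(vectorize_connectivity(cohort$connectivity), fraction)
  X <- standardize(residualize(fm, cohort$covariates,
                               c("age", "sex", "race", "motion")))
  Y <- standardize(residualize(clinical_matrix(cohort$clinical),
                               cohort$covariates, c("age", "sex", "race")))
  list(X = X, Y = Y, fm = fm)
}

# Independent-noise views with no linked structure (for calibration checks).
null_views <- function(n, p, q, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n), Y = matrix(rnorm(n * q), n))
}

# All set partitions of 1..n as lists of label vectors (restricted growth
# strings); used to sweep every community partition of a toy graph.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_label) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (lab in seq_len(next_label)) {
      recurse(c(labels, lab), max(next_label, lab + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}
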