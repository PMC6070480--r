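# Permutation significance testing with clinical-loading variate matching,
# FDR correction, and resampling-based stability selection of features.

#' Match canonical variates across refits by their clinical loadings
#'
#' Refitting sparse CCA on permuted or resampled data can reorder variates
#' (axis rotation) or flip their signs (axis reflection). Candidate variates
#' are aligned to the reference set by greedy one-to-one matching on the
#' absolute Pearson correlation between clinical loading vectors v; the sign
#' of the matched correlation gives the alignment sign.
#'
#' @param reference_v q x K matrix (or list of length-q vectors) of reference
#'   clinical loadings.
#' @param candidate_v q x K' matrix (or list) of candidate clinical loadings.
#' @param method "greedy" (default) or "optimal" (exhaustive one-to-one
#'   assignment maximizing the total |correlation|; intended for small K).
#' @return object of class `variate_match`: integer vector `assignment`
#'   (candidate index per reference variate), `signs` in {-1, +1},
#'   `match_scores` (|correlation| at each match).
#' @export
match_variates <- function(reference_v, candidate_v,
                           method = c("greedy", "optimal")) {
  method <- match.arg(method)
  R <- as.matrix(if (is.list(reference_v) && !is.data.frame(reference_v))
    do.call(cbind, reference_v) else reference_v)
  C <- as.matrix(if (is.list(candidate_v) && !is.data.frame(candidate_v))
    do.call(cbind, candidate_v) else candidate_v)
  if (nrow(R) != nrow(C)) {
    stop_("clinical loading dimensions differ: %d vs %d", nrow(R), nrow(C))
  }
  cors <- cor_columns(R, C)
  cors[is.na(cors)] <- 0
  if (method == "greedy" || ncol(C) == 1L) {
    g <- greedy_assign(cors)
    assignment <- g$candidate
    signs <- g$sign
    scores <- g$score
  } else {
    # exhaustive assignment over candidate permutations (small K only)
    K <- nrow(cors)
    perms <- all_permutations(ncol(cors))
    best_total <- -Inf
    assignment <- rep(NA_integer_, K)
    for (pr in perms) {
      take <- pr[seq_len(min(K, length(pr)))]
      total <- sum(abs(cors[cbind(seq_along(take), take)]))
      if (total > best_total) {
        best_total <- total
        assignment <- take
      }
    }
    signs <- sign(cors[cbind(seq_along(assignment), assignment)])
    signs[signs == 0] <- 1
    scores <- abs(cors[cbind(seq_along(assignment), assignment)])
  }
  structure(list(assignment = assignment, signs = signs,
                 match_scores = scores),
            class = "variate_match")
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

#' Empirical permutation p-value
#'
#' Fraction of null statistics at or above the observed one: count / B. The
#' literal count convention is the default (an observed value above every
#' null yields p = 0, reported as "< 1/B" when printed); `add_one` applies
#' the (count + 1) / (B + 1) correction recommended for small B.
#'
#' @param null_values numeric vector of null statistics (length B).
#' @param observed observed statistic.
#' @param add_one use the add-one convention.
#' @return scalar p-value in [0, 1].
#' @export
empirical_p <- function(null_values, observed, add_one = FALSE) {
  B <- length(null_values)
  cnt <- sum(null_values >= observed)
  if (add_one) (cnt + 1) / (B + 1) else cnt / B
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values, monotone and capped at 1.
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_("p-values must be numeric in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Permutation test of canonical variate significance
#'
#' The connectivity matrix is held fixed while the rows of the clinical
#' matrix are shuffled B times, breaking the subject linkage between views.
#' Each permuted dataset is refitted with identical parameters (K =
#' max(selected) components), the permuted variates are matched back to the
#' observed ones via [match_variates()], and the matched canonical
#' correlations form each variate's null distribution. The empirical p is
#' the fraction of null correlations at or above the variate's observed
#' correlation (`mode = "per-variate"`, the default) or at or above the mean
#' observed correlation over the selected variates (`mode = "aggregate"`);
#' q-values apply Benjamini-Hochberg correction across the selected
#' variates.
#'
#' @param X,Y prepared matrices (subjects aligned).
#' @param params `scca_params` used for the observed fit and every refit.
#' @param selected integer indices of the variates under test (default: all
#'   fitted components).
#' @param B number of permutations.
#' @param seed integer seed.
#' @param mode null-comparison convention, see above.
#' @param add_one use the (count + 1) / (B + 1) p-value convention.
#' @param reference optionally, the already-fitted observed `scca_model`.
#' @return object of class `permutation_result`: `B`, `null_r` (B x
#'   n_selected matrix), `observed_r`, `p`, `q`, `selected`, `seed`.
#' @export
permutation_test <- function(X, Y, params, selected = NULL, B = 1000L,
                             seed = 1L, mode = c("per-variate", "aggregate"),
                             add_one = FALSE, reference = NULL) {
  mode <- match.arg(mode)
  B <- assert_count(B, "B", lower = 1L)
  seed <- assert_count(seed, "seed")
  Xv <- as_values(X)
  Yv <- as_values(Y)
  if (is.null(reference)) reference <- fit_scca(Xv, Yv, params)
  K_fit <- length(reference$d)
  if (is.null(selected)) selected <- seq_len(K_fit)
  selected <- sort(unique(as.integer(selected)))
  if (any(selected < 1L | selected > K_fit)) {
    stop_("'selected' indices must lie in 1..%d", K_fit)
  }
  refit_params <- params
  refit_params$n_components <- max(selected)
  n <- nrow(Yv)
  null_r <- matrix(NA_real_, B, length(selected))
  set.seed(seed)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    mod_b <- fit_scca(Xv, Yv[perm, , drop = FALSE], refit_params)
    m <- match_variates(reference$v[, selected, drop = FALSE], mod_b$v)
    null_r[b, ] <- mod_b$r[m$assignment]
  }
  observed_r <- reference$r[selected]
  threshold <- if (mode == "aggregate") rep(mean(observed_r), length(selected))
  else observed_r
  p <- vapply(seq_along(selected), function(k) {
    empirical_p(null_r[, k], threshold[k], add_one = add_one)
  }, numeric(1L))
  q <- fdr_adjust(p)
  structure(
    list(B = B, null_r = null_r, observed_r = observed_r, p = p, q = q,
         selected = selected, mode = mode, add_one = add_one, seed = seed),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> B = %d permutations\n", x$B))
  tab <- data.frame(variate = x$selected,
                    observed_r = signif(x$observed_r, 4),
                    p = x$p, q = signif(x$q, 4))
  tab$p_label <- ifelse(x$p == 0, sprintf("< %g", 1 / x$B), format(x$p))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Stability selection of loadings by resampling
#'
#' Each of R draws rebuilds an n-subject sample from two-thirds of the
#' subjects taken without replacement plus the remaining third redrawn with
#' replacement from those two-thirds (bootstrap-flavoured resampling that
#' restores the original sample size). The model is refitted on each draw,
#' matched and sign-aligned to the reference variates via the clinical
#' loadings, and per-feature percentile confidence intervals are formed —
#' 99% for connectivity loadings, 95% for clinical loadings. A feature is
#' flagged stable (significant) when its interval excludes zero.
#'
#' @param X,Y prepared matrices.
#' @param params `scca_params` for every refit.
#' @param reference_model the observed `scca_model` the draws are aligned to.
#' @param selected variate indices to track (default: all components of the
#'   reference model).
#' @param R number of resampling draws (>= 2).
#' @param seed integer seed.
#' @param ci_connectivity,ci_clinical CI levels for the two views.
#' @return object of class `stability_result`: per selected variate,
#'   matrices `u_lower`/`u_upper`/`u_significant` (features x variates) and
#'   `v_lower`/`v_upper`/`v_significant` (items x variates), plus `R`,
#'   `seed`, CI levels.
#' @export
stability_resample <- function(X, Y, params, reference_model, selected = NULL,
                               R = 1000L, seed = 1L,
                               ci_connectivity = 0.99, ci_clinical = 0.95) {
  R <- assert_count(R, "R", lower = 2L)
  seed <- assert_count(seed, "seed")
  assert_scalar_number(ci_connectivity, "ci_connectivity", 0, 1)
  assert_scalar_number(ci_clinical, "ci_clinical", 0, 1)
  Xv <- as_values(X)
  Yv <- as_values(Y)
  n <- nrow(Xv)
  if (n < 6L) stop_("too few subjects for resampling: %d (need >= 6)", n)
  K_fit <- length(reference_model$d)
  if (is.null(selected)) selected <- seq_len(K_fit)
  selected <- sort(unique(as.integer(selected)))
  refit_params <- params
  refit_params$n_components <- max(selected)
  p <- ncol(Xv)
  q <- ncol(Yv)
  nk <- length(selected)
  u_draws <- array(NA_real_, c(p, nk, R))
  v_draws <- array(NA_real_, c(q, nk, R))
  n_base <- round(2 * n / 3)
  set.seed(seed)
  for (r in seq_len(R)) {
    base <- sample.int(n, n_base)
    extra <- base[sample.int(n_base, n - n_base, replace = TRUE)]
    idx <- c(base, extra)
    mod_r <- fit_scca(Xv[idx, , drop = FALSE], Yv[idx, , drop = FALSE],
                      refit_params)
    m <- match_variates(reference_model$v[, selected, drop = FALSE], mod_r$v)
    for (k in seq_len(nk)) {
      u_draws[, k, r] <- m$signs[k] * mod_r$u[, m$assignment[k]]
      v_draws[, k, r] <- m$signs[k] * mod_r$v[, m$assignment[k]]
    }
  }
  ci_bounds <- function(draws, level) {
    alpha <- (1 - level) / 2
    lower <- apply(draws, c(1L, 2L), stats::quantile, probs = alpha,
                   names = FALSE)
    upper <- apply(draws, c(1L, 2L), stats::quantile, probs = 1 - alpha,
                   names = FALSE)
    list(lower = lower, upper = upper,
         significant = lower > 0 | upper < 0)
  }
  u_ci <- ci_bounds(u_draws, ci_connectivity)
  v_ci <- ci_bounds(v_draws, ci_clinical)
  structure(
    list(R = R, selected = selected, seed = seed,
         ci_connectivity = ci_connectivity, ci_clinical = ci_clinical,
         u_lower = u_ci$lower, u_upper = u_ci$upper,
         u_significant = u_ci$significant,
         v_lower = v_ci$lower, v_upper = v_ci$upper,
         v_significant = v_ci$significant),
    class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability_result> R = %d draws; CI levels: connectivity %.0f%%, clinical %.0f%%\n",
    x$R, 100 * x$ci_connectivity, 100 * x$ci_clinical))
  tab <- data.frame(variate = x$selected,
                    stable_connectivity = colSums(x$u_significant),
                    stable_clinical = colSums(x$v_significant))
  print(tab, row.names = FALSE)
  invisible(x)
}
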