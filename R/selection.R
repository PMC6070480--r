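# Sparsity-parameter tuning by grid search over resampled subsets, and
# variate selection from the covariance-explained scree.

#' Grid search for the two L1 sparsity fractions
#'
#' For every (c1_frac, c2_frac) cell of a regular grid, the first canonical
#' variate is fitted on each of `n_draws` random subsamples (a fraction
#' `subsample_frac` of subjects, drawn without replacement) and the
#' first-variate canonical correlations are averaged. The chosen cell
#' attains the maximal mean correlation; ties prefer the sparser cell
#' (smaller c1_frac, then smaller c2_frac). Tuning belongs to the discovery
#' role only — a replication run reuses the frozen fractions.
#'
#' @param X,Y prepared connectivity and clinical matrices (subjects aligned).
#' @param grid_step grid increment in (0, 1]; cells are
#'   seq(grid_step, 1, by = grid_step) in each fraction (0 excluded as
#'   degenerate unless `include_zero = TRUE`).
#' @param n_draws number of random subsamples per cell.
#' @param subsample_frac fraction of subjects per draw (default two-thirds).
#' @param seed integer seed driving all draws; recorded in the result.
#' @param include_zero include frac = 0 cells (maximally sparse limit).
#' @param tol,max_iter convergence control passed to the component fits.
#' @return object of class `tuning_result`: `grid` (data.frame c1_frac,
#'   c2_frac, mean_first_r), `chosen`, `draw_seeds`, `n_draws`,
#'   `subsample_frac`.
#' @export
grid_search <- function(X, Y, grid_step = 0.1, n_draws = 10L,
                        subsample_frac = 2 / 3, seed = 1L,
                        include_zero = FALSE, tol = 1e-6, max_iter = 100L) {
  Xv <- as_values(X)
  Yv <- as_values(Y)
  if (nrow(Xv) != nrow(Yv)) stop_("X and Y subject counts differ")
  assert_scalar_number(grid_step, "grid_step")
  if (grid_step <= 0 || grid_step > 1) stop_("'grid_step' must be in (0, 1]")
  n_draws <- assert_count(n_draws, "n_draws", lower = 1L)
  n <- nrow(Xv)
  n_sub <- floor(subsample_frac * n)
  if (n_sub < 10L) {
    stop_("subsample too small: %d subjects (need at least 10)", n_sub)
  }
  fracs <- seq(grid_step, 1, by = grid_step)
  if (include_zero) fracs <- c(0, fracs)
  grid <- expand.grid(c1_frac = fracs, c2_frac = fracs,
                      KEEP.OUT.ATTRS = FALSE)
  p <- ncol(Xv)
  q <- ncol(Yv)
  seed <- assert_count(seed, "seed")
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max, n_draws)
  r_draws <- matrix(NA_real_, nrow(grid), n_draws)
  for (b in seq_len(n_draws)) {
    set.seed(draw_seeds[b])
    idx <- sample.int(n, n_sub)
    Xs <- Xv[idx, , drop = FALSE]
    Ys <- Yv[idx, , drop = FALSE]
    Zs <- crossprod(Xs, Ys)
    v0 <- svd(Zs, nu = 0L, nv = 1L)$v[, 1L]   # shared across cells
    for (g in seq_len(nrow(grid))) {
      fit <- fit_component(Zs, frac_to_bound(grid$c1_frac[g], p),
                           frac_to_bound(grid$c2_frac[g], q),
                           tol = tol, max_iter = max_iter, v0 = v0,
                           warn = FALSE)
      xs <- drop(Xs %*% fit$u)
      ys <- drop(Ys %*% fit$v)
      r_draws[g, b] <- if (stats::sd(xs) == 0 || stats::sd(ys) == 0) 0 else
        stats::cor(xs, ys)
    }
  }
  grid$mean_first_r <- rowMeans(r_draws)
  # argmax with parsimony tie-break: smaller c1_frac, then smaller c2_frac
  ord <- order(-grid$mean_first_r, grid$c1_frac, grid$c2_frac)
  best <- ord[1L]
  structure(
    list(grid = grid,
         chosen = c(c1_frac = grid$c1_frac[best], c2_frac = grid$c2_frac[best]),
         mean_first_r = grid$mean_first_r[best],
         draw_seeds = draw_seeds, n_draws = n_draws,
         subsample_frac = subsample_frac, seed = seed),
    class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf(
    "<tuning_result> %d grid cells x %d draws; chosen c1_frac = %.2f, c2_frac = %.2f (mean first r = %.3f)\n",
    nrow(x$grid), x$n_draws, x$chosen["c1_frac"], x$chosen["c2_frac"],
    x$mean_first_r))
  invisible(x)
}

#' Select canonical variates from the covariance-explained scree
#'
#' Returns the indices of the components whose covariance-explained fraction
#' lies strictly above the mean fraction (the dashed-line rule on a scree
#' plot). If no component exceeds the mean — all fractions equal — the first
#' component is returned.
#'
#' @param model an `scca_model` with at least one component.
#' @return integer vector of selected component indices.
#' @export
select_components <- function(model) {
  f <- covariance_explained(model)
  sel <- which(f > mean(f))
  if (length(sel) == 0L) sel <- 1L
  sort(sel)
}
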