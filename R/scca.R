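# Sparse CCA via rank-1 penalized matrix decomposition (PMD) with
# elastic-net constraints and deflation for multiple canonical variates.
#
# The optimization per variate is
#   maximize u' Z v  subject to ||u||2^2 <= 1, ||v||2^2 <= 1,
#                               ||u||1 <= c1, ||v||1 <= c2,
# with Z = X'Y, solved by alternating soft-thresholded updates. The L2
# bounds are fixed at 1 (elastic net with unit ridge budget); the L1 bounds
# are user-tuned through PMA-style fractions in [0, 1].

#' Soft-thresholding operator
#'
#' Componentwise sign(a) * max(|a| - delta, 0); the proximal operator of the
#' L1 penalty and the core update of the PMD solver.
#'
#' @param a numeric vector.
#' @param delta non-negative threshold.
#' @return numeric vector of the same length.
#' @export
soft_threshold <- function(a, delta) {
  assert_scalar_number(delta, "delta", lower = 0)
  sign(a) * pmax(abs(a) - delta, 0)
}

#' Project a vector onto the L2-unit sphere intersected with an L1 ball
#'
#' Returns w = S(a, delta) / ||S(a, delta)||2 where delta >= 0 is the
#' smallest soft-threshold making ||w||1 <= c. The L1-to-L2 ratio of the
#' thresholded vector is piecewise smooth and strictly decreasing in delta
#' between the sorted |a_i| knots, so delta solves a per-segment quadratic
#' in closed form (a bisection fallback guards numerically degenerate
#' segments). With c >= sqrt(p) no thresholding is needed and
#' w = a / ||a||2; at the fully sparse limit c = 1 the result is the signed
#' unit vector at the largest |a_i| (ties to the lowest index).
#'
#' @param a nonzero numeric vector.
#' @param c L1 bound, >= 1.
#' @return unit-L2 vector with ||w||1 <= c (up to 1e-6).
#' @export
l1_constrain <- function(a, c) {
  assert_scalar_number(c, "c", lower = 1)
  aa <- abs(a)
  amax <- max(aa)
  if (amax == 0) stop_("degenerate direction: input vector is all zero")
  if (c <= 1 + 1e-12) {
    # sparse limit; closed form avoids ties collapsing to zero
    i <- which.max(aa)
    w <- numeric(length(a))
    w[i] <- sign(a[i])
    return(w)
  }
  l2a <- sqrt(sum(a^2))
  if (sum(aa) / l2a <= c) return(a / l2a)
  # exact threshold: with the k largest |a_i| active on a segment, the
  # ratio condition (S1 - k d)^2 = c^2 (S2 - 2 d S1 + k d^2) is quadratic
  # in d; pick the smallest k whose segment brackets the crossing
  b <- sort(aa, decreasing = TRUE)
  S1 <- cumsum(b)
  S2 <- cumsum(b^2)
  k_seq <- seq_along(b)
  b_next <- c(b[-1L], 0)
  ratio_left <- (S1 - k_seq * b_next) /
    sqrt(pmax(S2 - 2 * b_next * S1 + k_seq * b_next^2, 0))
  k <- which(ratio_left >= c)[1L]
  delta <- NA_real_
  if (!is.na(k)) {
    A <- k * (k - c^2)
    Bq <- 2 * S1[k] * (c^2 - k)
    Cq <- S1[k]^2 - c^2 * S2[k]
    disc <- Bq^2 - 4 * A * Cq
    if (abs(A) > 1e-12 && disc >= 0) {
      roots <- (-Bq + c(-1, 1) * sqrt(disc)) / (2 * A)
      roots <- roots[roots >= b_next[k] - 1e-12 & roots <= b[k] + 1e-12]
      if (length(roots) > 0L) delta <- max(min(roots), 0)
    } else if (abs(A) <= 1e-12 && abs(Bq) > 1e-12) {
      delta <- -Cq / Bq
    }
  }
  if (is.na(delta) || delta < 0 || delta >= amax) {
    # fallback: bisection on the ratio
    lo <- 0
    hi <- amax
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      su <- pmax(aa - mid, 0)
      l2 <- sqrt(sum(su^2))
      if (l2 == 0 || sum(su) / l2 > c) lo <- mid else hi <- mid
      if (hi - lo < 1e-10 * amax) break
    }
    delta <- hi
  }
  su <- sign(a) * pmax(aa - delta, 0)
  su / sqrt(sum(su^2))
}

# PMA-style fraction -> L1 bound: c = max(1, frac * sqrt(dim)). frac = 1
# makes the constraint inactive (Cauchy-Schwarz); frac = 0 maps to the
# minimal feasible bound 1 (a single feature).
frac_to_bound <- function(frac, dim) {
  assert_scalar_number(frac, "frac", lower = 0, upper = 1)
  max(1, frac * sqrt(dim))
}

#' Fit one penalized rank-1 component of a cross-product matrix
#'
#' Alternating updates u <- l1_constrain(Z v, c1), v <- l1_constrain(Z' u,
#' c2), initialized at the leading right singular vector of Z, until the
#' maximum absolute change in (u, v) falls below `tol` or `max_iter` is
#' reached. The objective u' Z v is non-decreasing across iterations. The
#' returned d = u' Z v is non-negative (u is flipped if needed).
#'
#' @param Z p x q numeric cross-product matrix, not all zero.
#' @param c1,c2 L1 bounds (absolute, >= 1) for u and v.
#' @param tol convergence tolerance on the iterates.
#' @param max_iter maximum number of alternations.
#' @param v0 optional starting vector for v (defaults to the leading right
#'   singular vector); used to amortize the SVD across grid-search cells.
#' @param warn emit an R warning on non-convergence (default); internal
#'   resampling loops disable this and record the flag in their logs
#'   instead.
#' @return list with `u`, `v`, `d`, `iterations`, `converged`.
#' @export
fit_component <- function(Z, c1, c2, tol = 1e-6, max_iter = 100L, v0 = NULL,
                          warn = TRUE) {
  Z <- as.matrix(Z)
  if (all(Z == 0)) stop_("cross-product matrix Z is all zero")
  if (is.null(v0)) {
    v0 <- svd(Z, nu = 0L, nv = 1L)$v[, 1L]
  }
  v <- v0 / sqrt(sum(v0^2))
  u <- l1_constrain(drop(Z %*% v), c1)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    u_new <- l1_constrain(drop(Z %*% v), c1)
    v_new <- l1_constrain(drop(crossprod(Z, u_new)), c2)
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new
    v <- v_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && warn) {
    warning(sprintf("fit_component: no convergence in %d iterations", max_iter),
            call. = FALSE)
  }
  d <- drop(crossprod(u, Z %*% v))
  if (d < 0) {
    u <- -u
    d <- -d
  }
  list(u = u, v = v, d = d, iterations = iterations, converged = converged)
}

#' Sparse CCA parameter set
#'
#' @param c1_frac,c2_frac PMA-style sparsity fractions in [0, 1] for the
#'   connectivity (u) and clinical (v) loadings; 0 is maximally sparse, 1
#'   turns the L1 constraint off.
#' @param n_components number of canonical variates K to extract by
#'   deflation.
#' @param tol,max_iter convergence control for each component.
#' @return object of class `scca_params`.
#' @export
scca_params <- function(c1_frac = 0.5, c2_frac = 0.5, n_components = 1L,
                        tol = 1e-6, max_iter = 100L) {
  assert_scalar_number(c1_frac, "c1_frac", 0, 1)
  assert_scalar_number(c2_frac, "c2_frac", 0, 1)
  n_components <- assert_count(n_components, "n_components", lower = 1L)
  assert_scalar_number(tol, "tol", lower = 0)
  max_iter <- assert_count(max_iter, "max_iter", lower = 1L)
  structure(list(c1_frac = c1_frac, c2_frac = c2_frac,
                 n_components = n_components, tol = tol,
                 max_iter = max_iter),
            class = "scca_params")
}

#' Fit a sparse CCA model with K deflated components
#'
#' Component k is fitted on the deflated cross-product Z_k (Z_1 = X'Y,
#' Z_(k+1) = Z_k - d_k u_k v_k'). Each variate records its singular value
#' d_k, the canonical correlation r_k = cor(X u_k, Y v_k), the
#' covariance-explained fraction d_k / sum(d), and the per-subject brain and
#' clinical scores. Variates are oriented so that the clinical loading of
#' largest magnitude is positive (ties to the lowest item index), after
#' forcing d_k >= 0; jointly flipping (u, v) never changes d or r, so this
#' only fixes the reporting convention.
#'
#' @param X subjects x features connectivity matrix (a `feature_matrix` or
#'   plain matrix), already residualized/standardized as desired.
#' @param Y subjects x items clinical matrix (a `clinical_matrix` or plain
#'   matrix).
#' @param params an [scca_params()] object.
#' @return object of class `scca_model`: matrices `u` (p x K), `v` (q x K),
#'   vectors `d`, `r`, `cov_frac`, score matrices `x_scores`, `y_scores`
#'   (n x K), the `params`, and a per-component `convergence` log.
#' @export
fit_scca <- function(X, Y, params = scca_params()) {
  Xv <- as_values(X)
  Yv <- as_values(Y)
  if (nrow(Xv) != nrow(Yv)) {
    stop_("X has %d subjects but Y has %d; views must share subject order",
          nrow(Xv), nrow(Yv))
  }
  K <- params$n_components
  p <- ncol(Xv)
  q <- ncol(Yv)
  if (K > min(p, q)) {
    stop_("n_components (%d) exceeds min(p, q) = %d", K, min(p, q))
  }
  c1 <- frac_to_bound(params$c1_frac, p)
  c2 <- frac_to_bound(params$c2_frac, q)
  Z <- crossprod(Xv, Yv)
  u <- matrix(0, p, K)
  v <- matrix(0, q, K)
  d <- numeric(K)
  convergence <- vector("list", K)
  for (k in seq_len(K)) {
    fit <- fit_component(Z, c1, c2, tol = params$tol,
                         max_iter = params$max_iter, warn = FALSE)
    uk <- fit$u
    vk <- fit$v
    # sign convention: dominant clinical loading positive
    jmax <- which.max(abs(vk))
    if (vk[jmax] < 0) {
      uk <- -uk
      vk <- -vk
    }
    u[, k] <- uk
    v[, k] <- vk
    d[k] <- fit$d
    convergence[[k]] <- list(iterations = fit$iterations,
                             converged = fit$converged)
    Z <- Z - fit$d * (fit$u %*% t(fit$v))
  }
  x_scores <- Xv %*% u
  y_scores <- Yv %*% v
  r <- vapply(seq_len(K), function(k) {
    if (stats::sd(x_scores[, k]) == 0 || stats::sd(y_scores[, k]) == 0) {
      return(0)
    }
    stats::cor(x_scores[, k], y_scores[, k])
  }, numeric(1L))
  cov_frac <- if (sum(d) > 0) d / sum(d) else rep(NA_real_, K)
  structure(
    list(u = u, v = v, d = d, r = r, cov_frac = cov_frac,
         x_scores = x_scores, y_scores = y_scores,
         params = params, convergence = convergence,
         feature_index = if (inherits(X, "feature_matrix")) X$feature_index,
         item_index = if (inherits(Y, "clinical_matrix")) Y$item_index),
    class = "scca_model")
}

#' @export
print.scca_model <- function(x, ...) {
  K <- length(x$d)
  cat(sprintf("<scca_model> %d canonical variate(s), p = %d features, q = %d items\n",
              K, nrow(x$u), nrow(x$v)))
  tab <- data.frame(
    variate = seq_len(K),
    d = signif(x$d, 4),
    r = signif(x$r, 4),
    cov_frac = signif(x$cov_frac, 4),
    nnz_u = colSums(x$u != 0),
    nnz_v = colSums(x$v != 0))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Covariance explained by each canonical variate
#'
#' The default definition is d_k / sum_j d_j over the extracted components
#' (fractions sum to 1); `method = "d2"` uses squared singular values
#' d_k^2 / sum d_j^2 instead.
#'
#' @param model an `scca_model`.
#' @param method "d" (default) or "d2".
#' @return numeric vector of fractions summing to 1.
#' @export
covariance_explained <- function(model, method = c("d", "d2")) {
  method <- match.arg(method)
  d <- model$d
  if (length(d) == 0L || all(d == 0)) {
    stop_("all singular values are zero; covariance explained is undefined")
  }
  w <- if (method == "d") d else d^2
  w / sum(w)
}
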