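# The penalized matrix decomposition solver: soft thresholding, the
# L1-constrained unit projection, single-component fits against SVD
# oracles, deflation, and derived summaries.

test_that("soft thresholding shrinks componentwise", {
  expect_equal(soft_threshold(c(3, -3, 0.5), 1), c(2, -2, 0))
  a <- c(-2, 0, 1.7)
  expect_equal(soft_threshold(a, 0), a)
  expect_equal(soft_threshold(a, 2.5), c(0, 0, 0))
})

test_that("l1_constrain meets its contract on random inputs", {
  set.seed(1)
  for (rep in 1:20) {
    p <- sample(5:50, 1)
    a <- rnorm(p)
    c_bound <- runif(1, 1, sqrt(p))
    w <- l1_constrain(a, c_bound)
    expect_equal(sum(w^2), 1, tolerance = 1e-9)
    expect_lte(sum(abs(w)), c_bound + 1e-6)
  }
  expect_error(l1_constrain(rep(0, 4), 1.5), "zero")
})

test_that("l1_constrain is exact at the loose and fully sparse limits", {
  set.seed(2)
  a <- rnorm(12)
  # c >= sqrt(p): no thresholding
  expect_equal(l1_constrain(a, sqrt(12)), a / sqrt(sum(a^2)),
               tolerance = 1e-12)
  # c = 1: signed unit vector at the largest |a_i|
  w1 <- l1_constrain(a, 1)
  i_max <- which.max(abs(a))
  expect_equal(which(w1 != 0), i_max)
  expect_equal(w1[i_max], sign(a[i_max]))
  # tie -> lowest index
  a_tie <- c(2, -2, 0.5)
  expect_equal(l1_constrain(a_tie, 1), c(1, 0, 0))
})

test_that("l1_constrain matches a brute-force threshold-grid oracle", {
  set.seed(3)
  a <- rnorm(15)
  for (c_bound in c(1.3, 2, 3)) {
    w <- l1_constrain(a, c_bound)
    # oracle: smallest delta on a fine grid achieving the L1 bound
    deltas <- seq(0, max(abs(a)), length.out = 20001)
    for (d in deltas) {
      su <- soft_threshold(a, d)
      if (sum(su^2) == 0) next
      wg <- su / sqrt(sum(su^2))
      if (sum(abs(wg)) <= c_bound) break
    }
    expect_equal(w, wg, tolerance = 1e-3)
  }
})

test_that("fit_component recovers an exact rank-1 factorization", {
  set.seed(4)
  a <- rnorm(25); a <- a / sqrt(sum(a^2))
  b <- rnorm(10); b <- b / sqrt(sum(b^2))
  Z <- 3.7 * a %*% t(b)
  fit <- fit_component(Z, c1 = sqrt(25), c2 = sqrt(10))
  expect_gt(abs(cor(fit$u, a)), 0.9999)
  expect_gt(abs(cor(fit$v, b)), 0.9999)
  expect_equal(fit$d, 3.7, tolerance = 1e-6)
})

test_that("with inactive L1 constraints the fit matches the SVD oracle", {
  set.seed(5)
  for (rep in 1:5) {
    Z <- matrix(rnorm(30 * 20), 30)
    fit <- fit_component(Z, c1 = sqrt(30), c2 = sqrt(20))
    sv <- svd(Z, nu = 1, nv = 1)
    expect_gt(abs(cor(fit$u, sv$u[, 1])), 0.999)
    expect_gt(abs(cor(fit$v, sv$v[, 1])), 0.999)
    expect_equal(fit$d, sv$d[1], tolerance = 1e-4)
  }
})

test_that("axis-aligned cross-products are solved exactly", {
  Z <- diag(c(5, 1))
  fit <- fit_component(Z, c1 = 1, c2 = 1)
  expect_equal(fit$u, c(1, 0))
  expect_equal(fit$v, c(1, 0))
  expect_equal(fit$d, 5)
  expect_error(fit_component(matrix(0, 3, 3), 1, 1), "all zero")
})

test_that("the objective is non-decreasing across alternating iterations", {
  set.seed(6)
  Z <- matrix(rnorm(40 * 15), 40)
  # identical iterate prefixes: d after j iterations must be monotone in j
  d_seq <- vapply(1:12, function(j) {
    suppressWarnings(fit_component(Z, c1 = 0.4 * sqrt(40),
                                   c2 = 0.6 * sqrt(15), tol = 0,
                                   max_iter = j, warn = FALSE)$d)
  }, numeric(1))
  expect_true(all(diff(d_seq) >= -1e-10))
})

test_that("fit_scca recovers a planted single dimension at high SNR", {
  set.seed(7)
  n <- 400; p <- 200; q <- 30
  u_star <- numeric(p); u_star[sample(p, 10)] <- rnorm(10)
  u_star <- u_star / sqrt(sum(u_star^2))
  v_star <- numeric(q); v_star[sample(q, 5)] <- rnorm(5)
  v_star <- v_star / sqrt(sum(v_star^2))
  t_lat <- rnorm(n)
  X <- 3 * t_lat %*% t(u_star) + matrix(rnorm(n * p), n)
  Y <- 3 * t_lat %*% t(v_star) + matrix(rnorm(n * q), n)
  m <- fit_scca(standardize(X), standardize(Y), scca_params(0.5, 0.5))
  expect_gt(abs(cor(m$u[, 1], u_star)), 0.9)
  expect_gt(abs(cor(m$v[, 1], v_star)), 0.9)
  expect_gt(m$r[1], 0.7)
})

test_that("deflation exhausts a rank-1 structure", {
  set.seed(8)
  x <- rnorm(50)
  a <- rnorm(12); b <- rnorm(8)
  X <- x %*% t(a)                       # rank-1 X and Y -> rank-1 Z
  Y <- x %*% t(b)
  m <- fit_scca(X, Y, scca_params(1, 1, n_components = 2))
  expect_lt(m$d[2], 1e-6 * m$d[1])
  expect_error(fit_scca(X[1:10, ], Y, scca_params(1, 1)), "subject")
})

test_that("the sign convention and joint flips leave summaries unchanged", {
  set.seed(9)
  X <- matrix(rnorm(100 * 20), 100)
  Y <- matrix(rnorm(100 * 10), 100)
  m1 <- fit_scca(X, Y, scca_params(0.7, 0.7, n_components = 3))
  # dominant clinical loading positive in every variate
  for (k in 1:3) expect_gt(m1$v[which.max(abs(m1$v[, k])), k], 0)
  # negating one view flips loadings but not d, r, cov_frac
  m2 <- fit_scca(X, -Y, scca_params(0.7, 0.7, n_components = 3))
  expect_equal(m2$d, m1$d, tolerance = 1e-6)
  expect_equal(m2$r, m1$r, tolerance = 1e-6)
  expect_equal(m2$cov_frac, m1$cov_frac, tolerance = 1e-6)
})

test_that("decreasing the sparsity fraction never grows the support", {
  set.seed(10)
  X <- standardize(matrix(rnorm(120 * 40), 120))
  Y <- standardize(matrix(rnorm(120 * 12), 120))
  sizes <- vapply(seq(1, 0.1, by = -0.1), function(fr) {
    sum(fit_scca(X, Y, scca_params(fr, 1))$u[, 1] != 0)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("covariance explained normalizes the singular values", {
  model <- structure(list(d = c(2, 2, 2, 2)), class = "scca_model")
  expect_equal(covariance_explained(model), rep(0.25, 4))
  model$d <- c(3, 1)
  expect_equal(sum(covariance_explained(model)), 1, tolerance = 1e-12)
  expect_equal(covariance_explained(model, method = "d2"), c(0.9, 0.1))
  model$d <- c(0, 0)
  expect_error(covariance_explained(model), "zero")

  # rank-1 data: fractions ~ (1, 0)
  set.seed(11)
  x <- rnorm(60)
  X <- x %*% t(rnorm(10))
  Y <- x %*% t(rnorm(6))
  m <- fit_scca(X, Y, scca_params(1, 1, n_components = 2))
  expect_equal(covariance_explained(m), c(1, 0), tolerance = 1e-6)
})
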