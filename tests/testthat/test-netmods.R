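# Community-level loading summaries, label-permutation inference,
# cross-dimension overlap, and nodal strength.

test_that("loading matrices rebuild symmetrically from feature vectors", {
  fi <- data.frame(node_i = c(2, 1, 3), node_j = c(5, 4, 3))
  W <- build_loading_matrix(c(0.7, -0.2, 9), fi, 6)
  expect_equal(W[2, 5], 0.7)
  expect_equal(W[5, 2], 0.7)
  expect_equal(W[1, 4], -0.2)
  expect_equal(diag(W), rep(0, 6))   # diagonal zeroed even if indexed
  expect_equal(sum(W != 0), 4)

  # empty significant set -> zero matrix
  W0 <- build_loading_matrix(c(0.7, -0.2, 9), fi, 6,
                             significant_mask = rep(FALSE, 3))
  expect_equal(W0, matrix(0, 6, 6))

  # round trip through vectorization recovers the masked vector
  coh_m <- matrix(0, 6, 6)
  coh_m[2, 5] <- coh_m[5, 2] <- 0.7
  fm <- vectorize_connectivity(list(s = coh_m), tol = 1e-8)
  off <- fm$feature_index$node_i != fm$feature_index$node_j
  rebuilt <- build_loading_matrix(fm$values[1, off],
                                 fm$feature_index[off, ], 6)
  expect_equal(rebuilt, coh_m)

  expect_error(build_loading_matrix(c(1, 2), data.frame(node_i = c(1, 2),
                                                        node_j = c(2, 1)), 3),
               "duplicate")
})

test_that("within- and between-module loadings match hand evaluation", {
  comm <- c("m", "m", "m", "n")
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 2
  W[2, 3] <- W[3, 2] <- 3
  # (2 * 6) / (3 * 2) = 2
  expect_equal(within_module_loading(W, comm, "m"), 2)
  expect_equal(within_module_loading(matrix(0, 4, 4), comm, "m"), 0)
  expect_error(within_module_loading(W, comm, "n"), "singleton|>= 2")

  comm2 <- c("m", "m", "n", "n")
  W2 <- matrix(0, 4, 4)
  W2[1, 3] <- W2[3, 1] <- 1
  W2[2, 3] <- W2[3, 2] <- 3
  # pairs spanning m x n: (1,3)=1, (1,4)=0, (2,3)=3, (2,4)=0 -> 4 / 4 = 1
  expect_equal(between_module_loading(W2, comm2, "m", "n"), 1)
  # single-node communities: the lone edge value itself
  W3 <- matrix(0, 2, 2); W3[1, 2] <- W3[2, 1] <- 5
  expect_equal(between_module_loading(W3, c("a", "b"), "a", "b"), 5)
  expect_error(between_module_loading(W2, comm2, "m", "m"), "within")
})

test_that("a constant matrix yields that constant for every cell of every partition", {
  n <- 8
  cval <- 0.37
  W <- matrix(cval, n, n)
  diag(W) <- 0
  worst <- 0
  n_cells <- 0L
  for (part in all_partitions(n)) {
    labels <- unique(part)
    for (a in seq_along(labels)) {
      if (sum(part == labels[a]) >= 2) {
        worst <- max(worst, abs(within_module_loading(W, part, labels[a]) -
                                  cval))
        n_cells <- n_cells + 1L
      }
      for (b in seq_along(labels)) {
        if (b > a) {
          worst <- max(worst,
                       abs(between_module_loading(W, part, labels[a],
                                                  labels[b]) - cval))
          n_cells <- n_cells + 1L
        }
      }
    }
  }
  expect_gt(n_cells, 10000)   # every partition of the 8-node graph swept
  expect_lt(worst, 1e-12)
})

test_that("label permutation keeps community sizes and degenerates correctly", {
  comm <- rep(c("a", "b", "c"), times = c(4, 3, 3))
  W <- matrix(0.5, 10, 10)
  diag(W) <- 0
  res <- module_label_permutation(W, comm, B = 50, seed = 1)
  # constant loadings: every permuted statistic ties the observed one
  expect_true(all(res$p == 1, na.rm = TRUE))
  expect_equal(res$observed["a", "b"], 0.5)
  expect_true(isSymmetric(res$p))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("a planted hot community is detected by label permutation", {
  comm <- rep(c("hot", "cold1", "cold2"), times = c(5, 5, 5))
  W <- matrix(0, 15, 15)
  hot <- 1:5
  W[hot, hot] <- 1
  diag(W) <- 0
  res <- module_label_permutation(W, comm, B = 500, seed = 2)
  expect_lte(res$p["hot", "hot"], 0.01)
})

test_that("label-permutation p-values are uniform under exchangeable loadings", {
  set.seed(3)
  comm <- rep(c("a", "b"), each = 5)
  pvals <- replicate(200, {
    W <- matrix(0, 10, 10)
    vals <- rnorm(45)
    W[upper.tri(W)] <- vals
    W <- W + t(W)
    module_label_permutation(W, comm, B = 200,
                             seed = sample.int(1e6, 1))$p["a", "b"]
  })
  ks <- max(abs(sort(pvals) - ppoints(200, a = 0)))
  expect_lt(ks, 0.1)
})

test_that("common-edge overlap survives identical masks and dies on disjoint ones", {
  set.seed(4)
  n <- 100
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- pairs[sample(nrow(pairs), 49), , drop = FALSE]  # density ~ 0.01
  mask <- matrix(0L, n, n)
  mask[pick] <- 1L
  mask <- mask + t(mask)
  load_m <- mask * 0.5
  res <- common_edge_overlap(rep(list(mask), 4), rep(list(load_m), 4),
                             B = 200, seed = 5)
  # expected null-intersection density d^4 ~ 1e-8: the mask survives intact
  expect_equal(res$common_edge_mask, mask)
  expect_equal(res$n_candidate, 49L)
  expect_true(all(res$edges$mean_abs_loading == 0.5))
  # nodal strength sums incident mean absolute loadings
  expect_equal(res$nodal_strength, rowSums(abs(load_m * mask)))

  # pairwise-disjoint masks -> empty overlap
  m1 <- matrix(0L, 10, 10); m1[1, 2] <- m1[2, 1] <- 1L
  m2 <- matrix(0L, 10, 10); m2[3, 4] <- m2[4, 3] <- 1L
  res2 <- common_edge_overlap(list(m1, m2, m1, m2),
                              list(m1 * 1.0, m2 * 1.0, m1 * 1.0, m2 * 1.0),
                              B = 10, seed = 6)
  expect_equal(nrow(res2$edges), 0L)
  expect_equal(sum(res2$common_edge_mask), 0)

  # zero loadings on surviving edges -> zero nodal strength
  res3 <- common_edge_overlap(rep(list(mask), 4),
                              rep(list(mask * 0), 4), B = 50, seed = 7)
  expect_equal(res3$nodal_strength, rep(0, n))
})

test_that("more null repetitions can only shrink the surviving overlap", {
  set.seed(8)
  n <- 20
  masks <- lapply(1:4, function(d) {
    m <- matrix(0L, n, n)
    idx <- which(upper.tri(m), arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), 60), , drop = FALSE]
    m[pick] <- 1L
    m + t(m)
  })
  loads <- lapply(masks, function(m) m * 0.3)
  surv <- vapply(c(10, 100, 400), function(B) {
    nrow(common_edge_overlap(masks, loads, B = B, seed = 9)$edges)
  }, numeric(1))
  expect_true(all(diff(surv) <= 0))
})

test_that("nodal strength sums absolute incident loadings", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 2
  expect_equal(nodal_strength(W), c(3, 1, 2))
  W2 <- matrix(0, 4, 4)
  W2[1, 2] <- W2[2, 1] <- -0.5
  expect_equal(nodal_strength(W2), c(0.5, 0.5, 0, 0))
  expect_equal(nodal_strength(matrix(0, 5, 5)), rep(0, 5))
})
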