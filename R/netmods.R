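# Summaries of connectivity loading vectors on the brain graph: within- and
# between-community mean loadings, community-label permutation inference,
# cross-dimension common-edge overlap against a density-preserving null, and
# nodal loading strength.

#' Rebuild a node x node loading matrix from feature-indexed loadings
#'
#' Inverse of vectorization, restricted to the features flagged significant:
#' each retained loading is placed symmetrically at (node_i, node_j) and
#' (node_j, node_i); everything else, including the diagonal, is zero.
#'
#' @param loadings numeric vector of loadings, one per feature.
#' @param feature_index data.frame with `node_i`, `node_j` per feature.
#' @param n_nodes number of nodes of the target matrix.
#' @param significant_mask optional logical vector; features with FALSE are
#'   zeroed before placement.
#' @return symmetric n_nodes x n_nodes matrix with zero diagonal.
#' @export
build_loading_matrix <- function(loadings, feature_index, n_nodes,
                                 significant_mask = NULL) {
  n_nodes <- assert_count(n_nodes, "n_nodes", lower = 1L)
  fi <- as.data.frame(feature_index)
  if (length(loadings) != nrow(fi)) {
    stop_("loadings length (%d) does not match feature_index rows (%d)",
          length(loadings), nrow(fi))
  }
  if (any(fi$node_i < 1L | fi$node_j < 1L | fi$node_i > n_nodes |
          fi$node_j > n_nodes)) {
    stop_("feature_index contains node indices outside 1..%d", n_nodes)
  }
  key <- paste(pmin(fi$node_i, fi$node_j), pmax(fi$node_i, fi$node_j))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_("duplicate (node_i, node_j) entry in feature_index: (%s)",
          sub(" ", ", ", dup))
  }
  if (!is.null(significant_mask)) {
    if (length(significant_mask) != length(loadings)) {
      stop_("significant_mask length does not match loadings")
    }
    loadings <- ifelse(significant_mask, loadings, 0)
  }
  W <- matrix(0, n_nodes, n_nodes)
  W[cbind(fi$node_i, fi$node_j)] <- loadings
  W[cbind(fi$node_j, fi$node_i)] <- loadings
  diag(W) <- 0
  W
}

check_communities <- function(W, communities) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop_("W must be a square matrix")
  if (length(communities) != nrow(W)) {
    stop_("community vector length (%d) does not match node count (%d)",
          length(communities), nrow(W))
  }
  invisible(NULL)
}

#' Mean within-community connectivity loading
#'
#' sum over pairs i, j in community m of 2 W_ij / (|M| (|M| - 1)): the mean
#' edge loading over the |M| (|M| - 1) / 2 unordered node pairs inside the
#' community.
#'
#' @param W symmetric node x node loading matrix (zero diagonal).
#' @param communities per-node community labels.
#' @param m community label (must contain at least 2 nodes).
#' @return scalar mean loading.
#' @export
within_module_loading <- function(W, communities, m) {
  check_communities(W, communities)
  nodes <- which(communities == m)
  M <- length(nodes)
  if (M < 2L) {
    stop_("community '%s' has %d node(s); within-module loading needs >= 2",
          m, M)
  }
  sum(W[nodes, nodes]) / (M * (M - 1))
}

#' Mean between-community connectivity loading
#'
#' sum over i in community m, j in community n of W_ij / (|M| |N|): the mean
#' edge loading over all node pairs spanning the two communities.
#'
#' @param W symmetric node x node loading matrix.
#' @param communities per-node community labels.
#' @param m,n distinct community labels.
#' @return scalar mean loading.
#' @export
between_module_loading <- function(W, communities, m, n) {
  check_communities(W, communities)
  if (identical(m, n)) {
    stop_("m and n are the same community; use within_module_loading()")
  }
  nm <- which(communities == m)
  nn <- which(communities == n)
  if (length(nm) == 0L || length(nn) == 0L) {
    stop_("community '%s' has no nodes", if (length(nm) == 0L) m else n)
  }
  sum(W[nm, nn]) / (length(nm) * length(nn))
}

# All within/between cells for one labeling; returns a symmetric
# n_comm x n_comm matrix in the order of `labels`. Singleton communities get
# NA on the diagonal (within-loading undefined).
module_loading_cells <- function(W, communities, labels) {
  nc <- length(labels)
  out <- matrix(NA_real_, nc, nc, dimnames = list(labels, labels))
  for (a in seq_len(nc)) {
    sz <- sum(communities == labels[a])
    if (sz >= 2L) {
      out[a, a] <- within_module_loading(W, communities, labels[a])
    }
    if (a < nc) {
      for (b in (a + 1L):nc) {
        v <- between_module_loading(W, communities, labels[a], labels[b])
        out[a, b] <- v
        out[b, a] <- v
      }
    }
  }
  out
}

#' Community-level mean loadings with label-permutation significance
#'
#' Computes the community x community matrix of mean within/between loadings
#' and, for each cell, an empirical two-sided p-value from B permutations
#' that reassign community labels uniformly at random while preserving every
#' community's size: p = fraction of permuted |mean loading| at or above the
#' observed |mean loading|. q-values apply Benjamini-Hochberg correction
#' across the unique cells.
#'
#' @param W symmetric node x node loading matrix.
#' @param communities per-node community labels.
#' @param B number of label permutations.
#' @param seed integer seed.
#' @return object of class `module_loading_result`: `observed`, `p`, `q`
#'   (community x community matrices), `labels`, `B`, `seed`.
#' @export
module_label_permutation <- function(W, communities, B = 1000L, seed = 1L) {
  check_communities(W, communities)
  B <- assert_count(B, "B", lower = 1L)
  seed <- assert_count(seed, "seed")
  labels <- unique(communities)
  observed <- module_loading_cells(W, communities, labels)
  nc <- length(labels)
  exceed <- matrix(0, nc, nc)
  defined <- !is.na(observed)
  set.seed(seed)
  for (b in seq_len(B)) {
    perm_comm <- sample(communities)
    perm_cells <- module_loading_cells(W, perm_comm, labels)
    exceed <- exceed + (abs(perm_cells) >= abs(observed) &
                          defined & !is.na(perm_cells))
  }
  p <- exceed / B
  p[!defined] <- NA_real_
  # BH across the unique (upper-triangle incl. diagonal) defined cells
  ut <- upper.tri(p, diag = TRUE) & defined
  q <- matrix(NA_real_, nc, nc, dimnames = dimnames(p))
  q[ut] <- fdr_adjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(list(observed = observed, p = p, q = q, labels = labels,
                 B = B, seed = seed),
            class = "module_loading_result")
}

#' Cross-dimension common-edge overlap with a density-preserving null
#'
#' Binarized per-dimension significant-edge matrices are intersected (an
#' edge must be present in every dimension — equivalent to summing and
#' thresholding at the number of dimensions). The null model repeats, B
#' times, the intersection of independently drawn uniformly random edge sets
#' with the same per-dimension edge counts; any edge that appears in at
#' least one null intersection is eliminated from the candidate set.
#' Surviving edges carry the mean absolute loading across dimensions, and
#' per-node strengths sum the incident mean absolute loadings.
#'
#' @param masks list of binary (or logical) node x node matrices, one per
#'   dimension.
#' @param loadings list of node x node loading matrices, same length/shape.
#' @param B number of null repetitions.
#' @param seed integer seed.
#' @return object of class `overlap_result`: `common_edge_mask` (node x
#'   node binary), `edges` (data.frame node_i, node_j, mean_abs_loading),
#'   `nodal_strength`, `n_candidate`, `n_eliminated`, `B`, `seed`.
#' @export
common_edge_overlap <- function(masks, loadings, B = 1000L, seed = 1L) {
  B <- assert_count(B, "B", lower = 1L)
  seed <- assert_count(seed, "seed")
  if (!is.list(masks) || !is.list(loadings) ||
      length(masks) != length(loadings) || length(masks) < 1L) {
    stop_("'masks' and 'loadings' must be non-empty lists of equal length")
  }
  n_nodes <- nrow(masks[[1L]])
  for (d in seq_along(masks)) {
    if (!all(dim(masks[[d]]) == n_nodes) ||
        !all(dim(loadings[[d]]) == n_nodes)) {
      stop_("mask/loading shape mismatch in dimension %d", d)
    }
  }
  n_dims <- length(masks)
  pairs <- edge_enumeration(n_nodes)
  pair_idx <- cbind(pairs$node_i, pairs$node_j)
  n_pairs <- nrow(pairs)
  mask_vecs <- lapply(masks, function(m) (m[pair_idx] != 0))
  edge_counts <- vapply(mask_vecs, sum, integer(1L))
  candidate <- Reduce(`&`, mask_vecs)
  eliminated <- logical(n_pairs)
  set.seed(seed)
  for (b in seq_len(B)) {
    null_int <- rep(TRUE, n_pairs)
    for (d in seq_len(n_dims)) {
      draw <- logical(n_pairs)
      draw[sample.int(n_pairs, edge_counts[d])] <- TRUE
      null_int <- null_int & draw
      if (!any(null_int)) break
    }
    eliminated <- eliminated | null_int
  }
  surviving <- candidate & !eliminated
  mean_abs <- Reduce(`+`, lapply(loadings, function(L) abs(L[pair_idx]))) /
    n_dims
  mask_mat <- matrix(0L, n_nodes, n_nodes)
  mask_mat[pair_idx[surviving, , drop = FALSE]] <- 1L
  mask_mat <- mask_mat + t(mask_mat)
  mean_mat <- matrix(0, n_nodes, n_nodes)
  mean_mat[pair_idx[surviving, , drop = FALSE]] <- mean_abs[surviving]
  mean_mat <- mean_mat + t(mean_mat)
  structure(
    list(common_edge_mask = mask_mat,
         edges = data.frame(node_i = pairs$node_i[surviving],
                            node_j = pairs$node_j[surviving],
                            mean_abs_loading = mean_abs[surviving]),
         nodal_strength = nodal_strength(mean_mat),
         n_candidate = sum(candidate),
         n_eliminated = sum(candidate & eliminated),
         B = B, seed = seed),
    class = "overlap_result")
}

#' Nodal loading strength
#'
#' Per-node sum of absolute loadings over all incident edges: strength(i) =
#' sum_j |W_ij|.
#'
#' @param W symmetric node x node loading matrix.
#' @return non-negative numeric vector of length nrow(W).
#' @export
nodal_strength <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop_("W must be a square matrix")
  rowSums(abs(W))
}
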