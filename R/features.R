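# Feature preparation: vectorization of symmetric connectivity matrices,
# MAD-based edge selection, covariate residualization, standardization.

#' Enumerate unique connectivity features of an n-node symmetric matrix
#'
#' The enumeration convention is the upper triangle INCLUDING the diagonal in
#' row-major order: (1,1), (1,2), ..., (1,n), (2,2), ..., (n,n). A 264-node
#' matrix therefore yields 264 * 265 / 2 = 34,980 unique features. Diagonal
#' entries of a correlation matrix are constant at 1 and are removed later by
#' MAD filtering, so they never reach the analysis stage.
#'
#' @param n_nodes number of nodes.
#' @return data.frame with columns `node_i`, `node_j` (node_i <= node_j), one
#'   row per feature in enumeration order.
#' @export
feature_enumeration <- function(n_nodes) {
  n_nodes <- assert_count(n_nodes, "n_nodes", lower = 1L)
  i <- rep.int(seq_len(n_nodes), times = n_nodes - seq_len(n_nodes) + 1L)
  j <- sequence(n_nodes - seq_len(n_nodes) + 1L) +
    rep.int(seq_len(n_nodes), times = n_nodes - seq_len(n_nodes) + 1L) - 1L
  data.frame(node_i = i, node_j = j)
}

# Enumeration restricted to off-diagonal pairs (i < j); used by the synthetic
# generator and by loading-matrix reconstruction.
edge_enumeration <- function(n_nodes) {
  fi <- feature_enumeration(n_nodes)
  fi[fi$node_i < fi$node_j, , drop = FALSE]
}

#' Vectorize a set of per-subject symmetric connectivity matrices
#'
#' Produces the subjects x features matrix X entered into sparse CCA, one
#' column per unique feature under the row-major upper-triangle (including
#' diagonal) convention, together with the column -> (node_i, node_j) map.
#'
#' @param matrices list of square numeric matrices, one per subject, all with
#'   the same node order. Optionally named by subject id.
#' @param tol symmetry tolerance; any |M[i,j] - M[j,i]| above it is an error.
#' @return an object of class `feature_matrix` with elements `values`
#'   (subjects x features), `feature_index` (data.frame `column`, `node_i`,
#'   `node_j`) and `selection_meta` (populated by [filter_by_mad()]).
#' @export
vectorize_connectivity <- function(matrices, tol = 1e-8) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop_("'matrices' must be a non-empty list of square symmetric matrices")
  }
  n_nodes <- nrow(matrices[[1L]])
  ids <- names(matrices) %||% as.character(seq_along(matrices))
  for (s in seq_along(matrices)) {
    m <- matrices[[s]]
    if (!is.matrix(m) || nrow(m) != ncol(m)) {
      stop_("subject '%s': connectivity matrix is not square", ids[s])
    }
    if (nrow(m) != n_nodes) {
      stop_("subject '%s': matrix has %d nodes, expected %d (ragged input)",
            ids[s], nrow(m), n_nodes)
    }
    if (max(abs(m - t(m))) > tol) {
      stop_("subject '%s': connectivity matrix is not symmetric within %g",
            ids[s], tol)
    }
  }
  fi <- feature_enumeration(n_nodes)
  sel <- cbind(fi$node_i, fi$node_j)
  values <- t(vapply(matrices, function(m) m[sel], numeric(nrow(fi))))
  rownames(values) <- ids
  fi$column <- seq_len(nrow(fi))
  structure(
    list(values = values,
         feature_index = fi[, c("column", "node_i", "node_j")],
         selection_meta = NULL),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d connectivity features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$selection_meta)) {
    cat(sprintf("  MAD-filtered: kept %d of %d enumerated features (%.1f%%)\n",
                ncol(x$values), x$selection_meta$n_enumerated,
                100 * x$selection_meta$realized_fraction))
  }
  invisible(x)
}

#' Median absolute deviation (raw, unscaled)
#'
#' median(|x - median(x)|), with midpoint medians for even lengths. This is
#' the robust spread measure used to rank edge variability across subjects;
#' no normal-consistency constant is applied.
#'
#' @param values non-empty numeric vector.
#' @return non-negative scalar.
#' @export
mad_raw <- function(values) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop_("'values' must be a non-empty numeric vector")
  }
  stats::mad(values, constant = 1)
}

#' Retain the most variable connectivity features by MAD
#'
#' Ranks all enumerated features by their MAD across subjects and keeps the
#' top `floor(fraction * p)`. Zero-MAD features (in particular the constant
#' unit diagonal) always rank last and are never retained; with
#' `fraction = 1` this reduces to dropping all zero-MAD features. Ties are
#' broken by original feature order, so the result is deterministic.
#'
#' @param fm a `feature_matrix`.
#' @param fraction fraction of enumerated features to keep, in (0, 1].
#' @return a `feature_matrix` restricted to the selected columns, with
#'   `selection_meta` recording per-feature MADs and the realized fraction.
#' @export
filter_by_mad <- function(fm, fraction = 0.1) {
  if (!inherits(fm, "feature_matrix")) stop_("'fm' must be a feature_matrix")
  assert_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) stop_("'fraction' must be in (0, 1]")
  p <- ncol(fm$values)
  mads <- apply(fm$values, 2L, mad_raw)
  n_keep <- floor(fraction * p)
  ord <- order(-mads, seq_len(p))       # stable: ties by feature order
  keep <- ord[seq_len(n_keep)]
  keep <- keep[mads[keep] > 0]          # zero-MAD features are never retained
  keep <- sort(keep)
  out <- fm
  out$values <- fm$values[, keep, drop = FALSE]
  out$feature_index <- fm$feature_index[keep, , drop = FALSE]
  out$selection_meta <- list(
    mad = mads,
    requested_fraction = fraction,
    n_enumerated = p,
    n_retained = length(keep),
    realized_fraction = length(keep) / p)
  out
}

# Build a residualization design matrix from the covariate table.
# Categorical covariates get reference-level indicator coding; an intercept
# is always included.
covariate_design <- function(covariates, which) {
  covariates <- as.data.frame(covariates)
  if (length(which) == 0L) {
    return(matrix(1, nrow(covariates), 1L,
                  dimnames = list(NULL, "(Intercept)")))
  }
  missing_cov <- setdiff(which, names(covariates))
  if (length(missing_cov) > 0L) {
    stop_("covariates not found: %s", paste(missing_cov, collapse = ", "))
  }
  sub <- covariates[, which, drop = FALSE]
  if (anyNA(sub)) {
    bad <- which[vapply(sub, anyNA, logical(1L))]
    stop_("missing values in covariates: %s", paste(bad, collapse = ", "))
  }
  for (nm in names(sub)) {
    if (is.character(sub[[nm]]) || is.logical(sub[[nm]])) {
      sub[[nm]] <- factor(sub[[nm]])
    }
  }
  stats::model.matrix(~ ., data = sub)
}

#' Regress covariates out of a subjects x columns matrix
#'
#' Per-column ordinary least squares against an intercept plus the encoded
#' covariates; returns the residuals. Connectivity data are typically
#' residualized for age, sex, race and in-scanner motion, clinical data for
#' age, sex and race. With `which = character(0)` columns are mean-centered
#' only.
#'
#' @param matrix_ subjects x columns numeric matrix (or feature/clinical
#'   matrix object, residualized in place).
#' @param covariates per-subject covariate table, rows aligned with
#'   `matrix_`.
#' @param which character vector of covariate names to regress out.
#' @return same type as `matrix_`, with residualized values.
#' @export
residualize <- function(matrix_, covariates,
                        which = c("age", "sex", "race", "motion")) {
  vals <- as_values(matrix_)
  design <- covariate_design(covariates, which)
  if (nrow(design) != nrow(vals)) {
    stop_("covariate rows (%d) do not align with matrix rows (%d)",
          nrow(design), nrow(vals))
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1L):ncol(design)]]
    stop_("residualization design is rank-deficient; collinear columns: %s",
          paste(dropped, collapse = ", "))
  }
  res <- stats::lm.fit(design, vals)$residuals
  res <- as.matrix(res)
  dimnames(res) <- dimnames(vals)
  replace_values(matrix_, res)
}

replace_values <- function(template, values) {
  if (inherits(template, "feature_matrix") ||
      inherits(template, "clinical_matrix")) {
    template$values <- values
    return(template)
  }
  values
}

#' Standardize columns to mean zero and unit variance
#'
#' Uses the population standard deviation (denominator n), so a two-subject
#' column c(0, 2) maps to c(-1, 1). Zero-variance columns are an error: they
#' carry no information and would divide by zero.
#'
#' @param matrix_ subjects x columns matrix (or feature/clinical matrix
#'   object).
#' @return same type as `matrix_`, standardized.
#' @export
standardize <- function(matrix_) {
  vals <- as_values(matrix_)
  n <- nrow(vals)
  ctr <- sweep(vals, 2L, colMeans(vals))
  sds <- sqrt(colSums(ctr^2) / n)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop_("zero-variance column(s): %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  }
  out <- sweep(ctr, 2L, sds, "/")
  dimnames(out) <- dimnames(vals)
  replace_values(matrix_, out)
}

#' Assemble a clinical item matrix
#'
#' Light wrapper pairing the subjects x items values with item identifiers
#' (and optional screening-category labels), mirroring the `feature_matrix`
#' container for the connectivity view.
#'
#' @param values subjects x items numeric matrix.
#' @param item_index optional data.frame with columns `item` and (optionally)
#'   `category`.
#' @return object of class `clinical_matrix`.
#' @export
clinical_matrix <- function(values, item_index = NULL) {
  values <- as.matrix(values)
  if (is.null(item_index)) {
    item_index <- data.frame(
      item = colnames(values) %||% paste0("item_", seq_len(ncol(values))))
  }
  if (nrow(item_index) != ncol(values)) {
    stop_("item_index has %d rows but values has %d items",
          nrow(item_index), ncol(values))
  }
  structure(list(values = values, item_index = item_index),
            class = "clinical_matrix")
}

#' @export
print.clinical_matrix <- function(x, ...) {
  cat(sprintf("<clinical_matrix> %d subjects x %d items\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
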