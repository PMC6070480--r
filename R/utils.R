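# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_("'%s' must be a single number in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower ||
      x != floor(x)) {
    stop_("'%s' must be a single integer >= %d", name, lower)
  }
  invisible(as.integer(x))
}

# Extract a plain numeric matrix from feature_matrix / clinical_matrix /
# matrix inputs.
as_values <- function(x) {
  if (inherits(x, "feature_matrix") || inherits(x, "clinical_matrix")) {
    return(x$values)
  }
  if (is.data.frame(x)) return(as.matrix(x))
  if (is.matrix(x)) return(x)
  stop_("cannot interpret object of class '%s' as a subjects x features matrix",
        paste(class(x), collapse = "/"))
}

# Greedy one-to-one assignment maximizing |score|; deterministic tie-break by
# lowest (row, col) index. `scores` is reference x candidate. Returns a list
# with integer vectors `candidate` (per reference row), `sign`, `score`.
greedy_assign <- function(scores) {
  nr <- nrow(scores)
  nc <- ncol(scores)
  n_assign <- min(nr, nc)
  absmat <- abs(scores)
  cand <- rep(NA_integer_, nr)
  sgn <- rep(1, nr)
  sc <- rep(NA_real_, nr)
  row_free <- rep(TRUE, nr)
  col_free <- rep(TRUE, nc)
  for (step in seq_len(n_assign)) {
    sub <- absmat
    sub[!row_free, ] <- -Inf
    sub[, !col_free] <- -Inf
    # which.max scans column-major: ties resolve to the lowest linear index
    best <- which.max(sub)
    i <- (best - 1L) %% nr + 1L
    j <- (best - 1L) %/% nr + 1L
    cand[i] <- j
    s <- scores[i, j]
    sgn[i] <- if (is.na(s) || s >= 0) 1 else -1
    sc[i] <- absmat[i, j]
    row_free[i] <- FALSE
    col_free[j] <- FALSE
  }
  list(candidate = cand, sign = sgn, score = sc)
}

# Column-wise Pearson correlations between the columns of A and B, returned
# as a ncol(A) x ncol(B) matrix. Zero-variance columns yield NA -> treated as
# zero agreement by callers.
cor_columns <- function(A, B) {
  suppressWarnings(stats::cor(A, B))
}
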