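# Developmental analysis: age and sex effects on per-subject dimension
# scores via penalized-spline generalized additive models (mgcv).

#' Per-subject dimension scores for the developmental analysis
#'
#' Age and sex effects cannot be studied on scores computed from data that
#' had age and sex regressed out, so the developmental analysis uses feature
#' matrices residualized for race and motion only (connectivity) and race
#' only (clinical). In the default `"refit"` mode the sparse CCA model is
#' refitted on these partially residualized matrices and its variates are
#' matched (and sign-aligned) back to the fully residualized reference model
#' via the clinical loadings; scores are then X_partial u_k. The `"project"`
#' mode simply projects the partially residualized features onto the
#' reference loadings without refitting.
#'
#' @param X_partial connectivity matrix residualized for the non-development
#'   covariates only (feature index must match the reference model's).
#' @param Y_partial clinical matrix residualized the same way (required for
#'   `"refit"`).
#' @param model the reference `scca_model` (fully residualized fit).
#' @param selected variate indices to score (default: all components).
#' @param mode `"refit"` (default) or `"project"`.
#' @return list with `scores` (subjects x variates matrix, columns named
#'   dim1, dim2, ...), `match` (a `variate_match` for refit mode), and
#'   `model` (the refitted `scca_model`, refit mode only).
#' @export
dimension_scores <- function(X_partial, Y_partial = NULL, model,
                             selected = NULL, mode = c("refit", "project")) {
  mode <- match.arg(mode)
  Xv <- as_values(X_partial)
  if (ncol(Xv) != nrow(model$u)) {
    stop_("X_partial has %d features but the model has %d loadings",
          ncol(Xv), nrow(model$u))
  }
  K <- length(model$d)
  if (is.null(selected)) selected <- seq_len(K)
  selected <- sort(unique(as.integer(selected)))
  if (mode == "project") {
    scores <- Xv %*% model$u[, selected, drop = FALSE]
    colnames(scores) <- paste0("dim", selected)
    return(list(scores = scores, match = NULL, model = NULL))
  }
  if (is.null(Y_partial)) {
    stop_("Y_partial is required to refit the model in 'refit' mode")
  }
  refit <- fit_scca(Xv, Y_partial, model$params)
  m <- match_variates(model$v[, selected, drop = FALSE], refit$v)
  scores <- sapply(seq_along(selected), function(k) {
    m$signs[k] * drop(Xv %*% refit$u[, m$assignment[k]])
  })
  scores <- matrix(scores, nrow = nrow(Xv))
  colnames(scores) <- paste0("dim", selected)
  list(scores = scores, match = m, model = refit)
}

#' Age and sex effects on dimension scores via penalized-spline GAMs
#'
#' For each dimension score s the model s ~ sex + s(age) is fitted with
#' mgcv (thin-plate spline, basis dimension `k_basis`, REML smoothness
#' selection). The age effect is the penalized smooth (reported with its
#' effective degrees of freedom and approximate p-value), the sex effect is
#' the parametric coefficient. When `interaction = TRUE` an age-by-sex
#' interaction is tested in a separate model that adds a sex-specific smooth
#' deviation, s ~ sex + s(age) + s(age, by = sex). Benjamini-Hochberg FDR is
#' applied across dimensions separately within each effect family (age, sex,
#' interaction).
#'
#' @param scores subjects x dimensions numeric matrix (or a single vector).
#' @param age numeric vector of ages in years.
#' @param sex binary vector (0/1, logical, or two-level factor); the first
#'   level is the reference.
#' @param interaction also test the age-by-sex interaction.
#' @param k_basis spline basis dimension (default 10).
#' @return object of class `gam_result`: `table` (data.frame with dimension,
#'   effect, estimate, edf, p, q), `smooths` (per-dimension data.frame of
#'   age, fitted partial effect and standard error), `fits` (the mgcv
#'   objects).
#' @export
fit_age_sex_gam <- function(scores, age, sex, interaction = FALSE,
                            k_basis = 10L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 30L) stop_("need at least 30 subjects, got %d", n)
  if (length(age) != n || length(sex) != n) {
    stop_("age/sex length does not match the number of subjects")
  }
  if (stats::sd(age) == 0) stop_("age has no variation")
  sex_f <- if (is.factor(sex)) droplevels(sex) else factor(sex)
  if (nlevels(sex_f) != 2L) {
    stop_("sex must have exactly two observed levels, got %d", nlevels(sex_f))
  }
  dims <- colnames(scores) %||% paste0("dim", seq_len(ncol(scores)))
  rows <- list()
  smooths <- list()
  fits <- list()
  age_grid <- seq(min(age), max(age), length.out = 100L)
  for (kd in seq_len(ncol(scores))) {
    df <- data.frame(s = scores[, kd], age = age, sex = sex_f)
    fit <- mgcv::gam(s ~ sex + s(age, k = k_basis), data = df,
                     method = "REML")
    sm <- summary(fit)
    rows[[length(rows) + 1L]] <- data.frame(
      dimension = dims[kd], effect = "age",
      estimate = NA_real_, edf = sm$s.table[1L, "edf"],
      p = sm$s.table[1L, "p-value"])
    rows[[length(rows) + 1L]] <- data.frame(
      dimension = dims[kd], effect = "sex",
      estimate = unname(stats::coef(fit)[2L]), edf = NA_real_,
      p = sm$p.table[2L, "Pr(>|t|)"])
    if (interaction) {
      # ordered-factor by-smooth: the second smooth is the sex-specific
      # deviation from the common age trend
      df$sex_o <- as.ordered(df$sex)
      fit_i <- mgcv::gam(s ~ sex + s(age, k = k_basis) +
                           s(age, by = sex_o, k = k_basis),
                         data = df, method = "REML")
      smi <- summary(fit_i)
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = dims[kd], effect = "age_by_sex",
        estimate = NA_real_, edf = smi$s.table[2L, "edf"],
        p = smi$s.table[2L, "p-value"])
    }
    pred <- mgcv::predict.gam(
      fit, newdata = data.frame(age = age_grid,
                                sex = factor(levels(sex_f)[1L],
                                             levels = levels(sex_f))),
      type = "terms", terms = "s(age)", se.fit = TRUE)
    smooths[[dims[kd]]] <- data.frame(
      age = age_grid, fitted = as.numeric(pred$fit),
      se = as.numeric(pred$se.fit))
    fits[[dims[kd]]] <- fit
  }
  table_ <- do.call(rbind, rows)
  table_$q <- NA_real_
  for (fam in unique(table_$effect)) {
    sel <- table_$effect == fam
    table_$q[sel] <- fdr_adjust(table_$p[sel])
  }
  rownames(table_) <- NULL
  structure(list(table = table_, smooths = smooths, fits = fits,
                 k_basis = k_basis),
            class = "gam_result")
}

#' @export
print.gam_result <- function(x, ...) {
  cat("<gam_result> age/sex effects on dimension scores\n")
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 4)
  tab$edf <- signif(tab$edf, 4)
  tab$p <- signif(tab$p, 4)
  tab$q <- signif(tab$q, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
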