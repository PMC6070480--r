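# Synthetic cohorts with planted sparse canonical structure linking a
# connectivity view (symmetric node x node correlation matrices) to an
# ordinal clinical item view, plus age/sex/race/motion confound effects on
# both views. Ground truth is returned alongside the data so every pipeline
# stage can be tested for recovery without access to restricted cohorts.

#' Default community partition for a 264-node parcellation
#'
#' Thirteen functional systems plus an unsorted group, with sizes summing to
#' 264, qualitatively matching the a priori communities of a widely used
#' 264-node functional parcellation.
#'
#' @return named integer vector of community sizes.
#' @export
default_communities_264 <- function() {
  c(somatomotor_hand = 30L, somatomotor_mouth = 5L, cingulo_opercular = 14L,
    auditory = 13L, default_mode = 58L, memory = 5L, visual = 31L,
    frontoparietal = 25L, salience = 18L, subcortical = 13L,
    ventral_attention = 9L, dorsal_attention = 11L, cerebellar = 4L,
    uncertain = 28L)
}

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the discovery cohort of a developmental community sample:
#' 663 subjects, a 264-node parcellation with 14 a priori communities, 111
#' ordinal screening items, and four latent dimensions linking sparse sets of
#' connectivity edges to sparse sets of clinical items, with modest
#' confounding by age, sex, race and in-scanner motion on both views.
#'
#' @param n_subjects number of subjects.
#' @param n_nodes number of parcellation nodes.
#' @param community_sizes integer vector of community sizes summing to
#'   `n_nodes`; names, if present, become community labels.
#' @param n_items number of ordinal clinical items.
#' @param n_latent number of planted latent dimensions K*.
#' @param conn_support_sizes number of nonzero edge loadings per latent
#'   dimension (recycled to length K*).
#' @param clin_support_sizes number of nonzero item loadings per latent
#'   dimension (recycled).
#' @param effect_scales latent effect scales sigma_k (recycled).
#' @param confound_effects list with elements `connectivity` and `clinical`,
#'   each a named vector of effect scales per covariate (age, sex, race,
#'   motion).
#' @param noise_sd standard deviation of the edge- and item-level noise.
#' @param item_levels number of ordinal levels per clinical item (>= 2).
#' @param seed integer seed; one seeded generator drives all draws.
#' @param u_true,v_true optional lists of explicit unit-norm sparse truth
#'   vectors (length K*) overriding the random supports; edge vectors are
#'   indexed by the off-diagonal enumeration of [edge_enumeration()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 663L,
                          n_nodes = 264L,
                          community_sizes = default_communities_264(),
                          n_items = 111L,
                          n_latent = 4L,
                          conn_support_sizes = 50L,
                          clin_support_sizes = 15L,
                          effect_scales = c(3, 2.5, 2, 1.5),
                          confound_effects = list(
                            connectivity = c(age = 0.5, sex = 0.3,
                                             race = 0.2, motion = 0.5),
                            clinical = c(age = 0.5, sex = 0.3, race = 0.2)),
                          noise_sd = 1,
                          item_levels = 4L,
                          seed = 1L,
                          u_true = NULL,
                          v_true = NULL) {
  n_subjects <- assert_count(n_subjects, "n_subjects", lower = 2L)
  n_nodes <- assert_count(n_nodes, "n_nodes", lower = 2L)
  n_items <- assert_count(n_items, "n_items", lower = 1L)
  n_latent <- assert_count(n_latent, "n_latent", lower = 0L)
  item_levels <- assert_count(item_levels, "item_levels", lower = 2L)
  seed <- assert_count(seed, "seed")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (sum(community_sizes) != n_nodes) {
    stop_("community_sizes sums to %d, but n_nodes is %d",
          sum(community_sizes), n_nodes)
  }
  if (any(community_sizes < 1)) stop_("community_sizes must be positive")
  p_edges <- n_nodes * (n_nodes - 1L) / 2L
  K <- n_latent
  if (K > 0L) {
    conn_support_sizes <- rep_len(as.integer(conn_support_sizes), K)
    clin_support_sizes <- rep_len(as.integer(clin_support_sizes), K)
    effect_scales <- rep_len(as.numeric(effect_scales), K)
    if (any(conn_support_sizes < 1L | conn_support_sizes > p_edges)) {
      stop_("conn_support_sizes must lie in 1..%d (off-diagonal edges)",
            p_edges)
    }
    if (any(clin_support_sizes < 1L | clin_support_sizes > n_items)) {
      stop_("clin_support_sizes must lie in 1..%d", n_items)
    }
    if (any(effect_scales < 0)) stop_("effect_scales must be non-negative")
  } else {
    conn_support_sizes <- integer(0)
    clin_support_sizes <- integer(0)
    effect_scales <- numeric(0)
  }
  for (vn in c("u_true", "v_true")) {
    vv <- get(vn)
    if (!is.null(vv)) {
      if (!is.list(vv) || length(vv) != K) {
        stop_("'%s' must be a list of %d vectors", vn, K)
      }
      dim_needed <- if (vn == "u_true") p_edges else n_items
      for (k in seq_len(K)) {
        if (length(vv[[k]]) != dim_needed) {
          stop_("'%s[[%d]]' must have length %d", vn, k, dim_needed)
        }
      }
    }
  }
  if (is.null(names(community_sizes))) {
    names(community_sizes) <- paste0("community_", seq_along(community_sizes))
  }
  structure(
    list(n_subjects = n_subjects, n_nodes = n_nodes,
         community_sizes = community_sizes, n_items = n_items,
         n_latent = K, conn_support_sizes = conn_support_sizes,
         clin_support_sizes = clin_support_sizes,
         effect_scales = effect_scales,
         confound_effects = confound_effects, noise_sd = noise_sd,
         item_levels = item_levels, seed = seed,
         u_true = u_true, v_true = v_true),
    class = "cohort_config")
}

# Unit-norm vector with a random support of the requested size.
random_sparse_unit <- function(dim, support) {
  idx <- sample.int(dim, support)
  w <- numeric(dim)
  w[idx] <- stats::rnorm(support)
  w / sqrt(sum(w^2))
}

# Standardized (mean 0, sd 1) encoded covariate columns for confound
# injection. Race contributes its reference-coded dummies.
confound_design <- function(covariates) {
  cols <- list(
    age = scale(covariates$age)[, 1L],
    sex = scale(covariates$sex)[, 1L],
    motion = scale(log(covariates$motion))[, 1L])
  race_mm <- stats::model.matrix(~ race, data = covariates)[, -1L,
                                                            drop = FALSE]
  race_cols <- lapply(seq_len(ncol(race_mm)), function(j) {
    x <- race_mm[, j]
    if (stats::sd(x) == 0) rep(0, length(x)) else scale(x)[, 1L]
  })
  names(race_cols) <- rep("race", length(race_cols))
  c(cols[c("age", "sex")], race_cols, cols["motion"])
}

#' Generate a synthetic cohort with planted canonical structure
#'
#' Per subject, latent factors t_k ~ N(0, 1) drive both views. Edge
#' pre-values are z_ij = mu_ij + sum_k sigma_k t_k u*_k(ij) + confounds +
#' noise, squashed into (-1, 1) by tanh, symmetrized, with unit diagonal;
#' the baseline mu is elevated inside communities so block structure is
#' visible. Clinical latents y_q = sum_k sigma_k t_k v*_kq + confounds +
#' noise are discretized to ordinal levels at fixed equal-mass population
#' quantiles. Confound effects enter each view along fixed random unit
#' directions scaled by the configured effect sizes, applied to
#' standardized covariate encodings. Fully deterministic for a fixed seed.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: `connectivity` (list of
#'   symmetric matrices), `clinical` (subjects x items integer matrix),
#'   `covariates` (data.frame subject_id, age, sex, race, motion),
#'   `communities` (data.frame node_id, node_name, community_label),
#'   `truth` (u_true/v_true matrices, latent_scores, confound_coefs,
#'   edge_index), and the `config` (seed included).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_("'config' must be built with cohort_config()")
  }
  set.seed(config$seed)
  n <- config$n_subjects
  n_nodes <- config$n_nodes
  K <- config$n_latent
  edge_index <- edge_enumeration(n_nodes)
  p_edges <- nrow(edge_index)

  # covariates: adolescent age range, balanced sex, 3-level race,
  # log-normal in-scanner motion (mean framewise displacement, mm)
  covariates <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    age = stats::runif(n, 8, 22),
    sex = stats::rbinom(n, 1L, 0.5),
    race = sample(c("groupA", "groupB", "groupC"), n, replace = TRUE,
                  prob = c(0.5, 0.4, 0.1)),
    motion = stats::rlnorm(n, meanlog = log(0.08), sdlog = 0.5),
    stringsAsFactors = FALSE)

  # planted truth
  u_true <- matrix(0, p_edges, max(K, 0L))
  v_true <- matrix(0, config$n_items, max(K, 0L))
  for (k in seq_len(K)) {
    u_true[, k] <- if (!is.null(config$u_true)) config$u_true[[k]] else
      random_sparse_unit(p_edges, config$conn_support_sizes[k])
    v_true[, k] <- if (!is.null(config$v_true)) config$v_true[[k]] else
      random_sparse_unit(config$n_items, config$clin_support_sizes[k])
  }
  latent <- matrix(stats::rnorm(n * max(K, 1L)), n)[, seq_len(K),
                                                    drop = FALSE]

  # community labels in node order
  comm_labels <- rep(names(config$community_sizes),
                     times = config$community_sizes)
  within <- comm_labels[edge_index$node_i] == comm_labels[edge_index$node_j]
  mu <- ifelse(within, 0.35, 0.10)   # pre-value baseline, elevated in-block

  # confound directions and coefficient tables
  design <- confound_design(covariates)
  build_confound <- function(effects, dim) {
    coefs <- matrix(0, dim, length(design),
                    dimnames = list(NULL, names(design)))
    contrib <- matrix(0, n, dim)
    effects <- effects %||% numeric(0)
    for (j in seq_along(design)) {
      s <- unname(effects[names(design)[j]])
      if (length(s) == 0L || is.na(s) || s == 0) next
      w <- stats::rnorm(dim)
      w <- s * w / sqrt(sum(w^2))
      coefs[, j] <- w
      contrib <- contrib + design[[j]] %*% t(w)
    }
    list(coefs = coefs, contrib = contrib)
  }
  conf_conn <- build_confound(config$confound_effects$connectivity, p_edges)
  conf_clin <- build_confound(config$confound_effects$clinical,
                              config$n_items)

  # connectivity pre-values -> tanh squash -> symmetric matrices
  signal_conn <- if (K > 0L) {
    latent %*% (t(u_true) * config$effect_scales)
  } else matrix(0, n, p_edges)
  pre <- matrix(mu, n, p_edges, byrow = TRUE) + signal_conn +
    conf_conn$contrib +
    matrix(stats::rnorm(n * p_edges, sd = config$noise_sd), n)
  edge_vals <- tanh(pre)
  sel <- cbind(edge_index$node_i, edge_index$node_j)
  sel_t <- sel[, 2:1, drop = FALSE]
  connectivity <- lapply(seq_len(n), function(s) {
    m <- diag(1, n_nodes)
    m[sel] <- edge_vals[s, ]
    m[sel_t] <- edge_vals[s, ]
    m
  })
  names(connectivity) <- covariates$subject_id

  # clinical latents -> fixed equal-mass quantile discretization
  signal_clin <- if (K > 0L) {
    latent %*% (t(v_true) * config$effect_scales)
  } else matrix(0, n, config$n_items)
  y_latent <- signal_clin + conf_clin$contrib +
    matrix(stats::rnorm(n * config$n_items, sd = config$noise_sd), n)
  L <- config$item_levels
  clinical <- apply(y_latent, 2L, function(y) {
    cuts <- stats::quantile(y, probs = seq_len(L - 1L) / L, names = FALSE)
    findInterval(y, cuts)
  })
  clinical <- matrix(as.integer(clinical), n,
                     dimnames = list(covariates$subject_id,
                                     sprintf("item%03d", seq_len(config$n_items))))

  communities <- data.frame(
    node_id = seq_len(n_nodes),
    node_name = sprintf("node%03d", seq_len(n_nodes)),
    community_label = comm_labels,
    stringsAsFactors = FALSE)

  structure(
    list(connectivity = connectivity,
         clinical = clinical,
         covariates = covariates,
         communities = communities,
         truth = list(u_true = u_true, v_true = v_true,
                      latent_scores = latent,
                      confound_coefs = list(connectivity = conf_conn$coefs,
                                            clinical = conf_clin$coefs),
                      edge_index = edge_index),
         config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d nodes (%d communities), %d items, K* = %d (seed %d)\n",
    length(x$connectivity), x$config$n_nodes,
    length(x$config$community_sizes), x$config$n_items, x$config$n_latent,
    x$config$seed))
  invisible(x)
}

#' Recovery of planted loadings by a fitted model
#'
#' Aligns estimated canonical variates to the planted dimensions by greedy
#' one-to-one matching on the average of the two per-view absolute loading
#' correlations, which makes the report invariant to component order and
#' joint sign flips. The per-dimension `recovery` is the smaller of the two
#' matched per-view |correlations|, so a dimension counts as recovered only
#' when both its connectivity and its clinical loadings are. Estimated
#' connectivity loadings are mapped into the truth's edge space through the
#' model's feature index; diagonal features and edges dropped by filtering
#' are excluded from the comparison.
#'
#' @param truth the `truth` element of a `synthetic_cohort` (or the cohort
#'   itself).
#' @param model a fitted `scca_model`.
#' @param feature_index optional feature index for the model's u rows;
#'   defaults to the index stored in the model.
#' @return data.frame with one row per planted dimension: `dim`,
#'   `component` (matched estimated component), `recovery` =
#'   min(recovery_u, recovery_v) in [0, 1], `recovery_u`, `recovery_v` (the
#'   per-view sign-aligned absolute correlations).
#' @export
score_recovery <- function(truth, model, feature_index = NULL) {
  if (inherits(truth, "synthetic_cohort")) truth <- truth$truth
  feature_index <- feature_index %||% model$feature_index
  if (is.null(feature_index)) {
    stop_("no feature index available to align connectivity loadings")
  }
  if (nrow(truth$v_true) != nrow(model$v)) {
    stop_("item dimension mismatch: truth has %d items, model has %d",
          nrow(truth$v_true), nrow(model$v))
  }
  K_true <- ncol(truth$u_true)
  K_est <- length(model$d)
  edge_key <- paste(truth$edge_index$node_i, truth$edge_index$node_j)
  fi <- as.data.frame(feature_index)
  offdiag <- fi$node_i != fi$node_j
  model_key <- paste(pmin(fi$node_i, fi$node_j), pmax(fi$node_i, fi$node_j))
  pos <- match(model_key[offdiag], edge_key)
  if (anyNA(pos)) stop_("model features outside the truth's edge space")
  U_est <- model$u[offdiag, , drop = FALSE]
  U_true <- truth$u_true[pos, , drop = FALSE]
  cors_u <- matrix(0, K_true, K_est)
  cors_v <- matrix(0, K_true, K_est)
  for (j in seq_len(K_true)) {
    for (k in seq_len(K_est)) {
      cu <- suppressWarnings(stats::cor(U_true[, j], U_est[, k]))
      cv <- suppressWarnings(stats::cor(truth$v_true[, j], model$v[, k]))
      cors_u[j, k] <- if (is.na(cu)) 0 else cu
      cors_v[j, k] <- if (is.na(cv)) 0 else cv
    }
  }
  g <- greedy_assign((abs(cors_u) + abs(cors_v)) / 2)
  matched <- !is.na(g$candidate)
  ru <- rv <- rep(0, K_true)
  ru[matched] <- abs(cors_u[cbind(which(matched), g$candidate[matched])])
  rv[matched] <- abs(cors_v[cbind(which(matched), g$candidate[matched])])
  data.frame(
    dim = seq_len(K_true),
    component = g$candidate,
    recovery = pmin(ru, rv),
    recovery_u = ru,
    recovery_v = rv)
}
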