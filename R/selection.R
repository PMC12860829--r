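#' Stage 1: cross-cohort stability filter
#'
#' Drops feature columns with variance below `var_threshold` in either
#' cohort, or with inconsistent distributions across cohorts (two-sample
#' Kolmogorov-Smirnov p below `ks_alpha`). The audit records which rule
#' fired for every removal.
#'
#' @param table_a,table_b `pf_feature_table`s sharing columns.
#' @param var_threshold Minimum per-cohort column variance (default 1e-8).
#' @param ks_alpha KS significance level for distribution inconsistency
#'   (default 0.01).
#' @return List: `retained` (column names), `audit` (data.frame of removed
#'   columns with `reason`).
#' @export
stability_filter <- function(table_a, table_b, var_threshold = 1e-8,
                             ks_alpha = 0.01) {
  A <- table_a$values; B <- table_b$values
  if (!identical(colnames(A), colnames(B))) stop("column mismatch")
  va <- apply(A, 2, var); vb <- apply(B, 2, var)
  low_var <- !is.finite(va) | !is.finite(vb) | va < var_threshold |
    vb < var_threshold
  ks_bad <- rep(FALSE, ncol(A))
  for (j in which(!low_var)) {
    p <- suppressWarnings(ks.test(A[, j], B[, j])$p.value)
    ks_bad[j] <- is.finite(p) && p < ks_alpha
  }
  removed <- low_var | ks_bad
  audit <- data.frame(
    column = colnames(A)[removed],
    reason = ifelse(low_var[removed], "low_variance", "ks_distribution"),
    stringsAsFactors = FALSE)
  list(retained = colnames(A)[!removed], audit = audit)
}

audit_df <- function(cols, reason) {
  data.frame(column = cols, reason = rep(reason, length(cols)),
             stringsAsFactors = FALSE)
}

# Log-spaced lambda grid from lambda_max (smallest lambda zeroing all
# coefficients) down 4 decades.
lambda_grid <- function(X, y, alpha, n = 100L, decades = 4) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xc, yc))) / (nrow(X) * max(alpha, 1e-3))
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n))
}

#' Elastic-net path with cross-validated lambda selection
#'
#' Coordinate-descent minimization of
#' `(1/2n) ||y - X b||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||^2)`
#' over a decreasing lambda grid with warm starts, for a single
#' (one-vs-rest) response. `lambda*` is chosen by the minimum mean
#' cross-validated MSE; the returned coefficients are refit on the full data
#' at `lambda*`.
#'
#' @param X Numeric matrix (standardized columns).
#' @param y Numeric response (one-vs-rest indicator).
#' @param alpha Elastic-net mixing parameter in [0, 1].
#' @param lambdas Optional decreasing lambda grid (default: 100 log-spaced
#'   values over 4 decades from `lambda_max`).
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param tol Coordinate-descent convergence tolerance (largest coefficient
#'   update in a sweep).
#' @param maxit Sweep budget per lambda.
#' @return List: `lambda` (grid), `cvm` (mean CV MSE per lambda),
#'   `lambda_min`, `beta` (coefficients at `lambda_min`), `intercept`,
#'   `retained` (names of nonzero coefficients), `beta_path`.
#' @export
elastic_net_path <- function(X, y, alpha, lambdas = NULL, folds = 10L,
                             seed = 1L, tol = 2e-5, maxit = 600L) {
  X <- as.matrix(X)
  if (is.null(lambdas)) lambdas <- lambda_grid(X, y, alpha)
  lambdas <- sort(lambdas, decreasing = TRUE)
  n <- nrow(X)
  set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  if (min(table(fold_id)) < 2) stop("degenerate fold")
  mse <- matrix(NA_real_, folds, length(lambdas))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2) stop("degenerate fold (single class)")
    fit <- cpp_enet_path(X[tr, , drop = FALSE], y[tr], alpha, lambdas,
                         tol, maxit)
    pred <- X[!tr, , drop = FALSE] %*% fit$beta +
      matrix(fit$intercept, sum(!tr), length(lambdas), byrow = TRUE)
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(mse)
  li <- which.min(cvm)
  full <- cpp_enet_path(X, y, alpha, lambdas, tol, maxit)
  beta <- setNames(full$beta[, li], colnames(X))
  list(lambda = lambdas, cvm = cvm, lambda_min = lambdas[li],
       beta = beta, intercept = full$intercept[li],
       retained = names(beta)[beta != 0], beta_path = full$beta)
}

# One-vs-rest elastic net over all classes: support union and the p x K
# per-class weight profile matrix.
enet_multiclass <- function(X, labels, alpha, folds = 10L, seed = 1L) {
  classes <- sort(unique(labels))
  W <- matrix(0, ncol(X), length(classes),
              dimnames = list(colnames(X), classes))
  lam <- numeric(length(classes))
  for (k in seq_along(classes)) {
    fit <- elastic_net_path(X, as.numeric(labels == classes[k]), alpha,
                            folds = folds, seed = seed + k)
    W[, k] <- fit$beta
    lam[k] <- fit$lambda_min
  }
  support <- rownames(W)[rowSums(W != 0) > 0]
  list(weights = W, support = support, lambda_min = lam)
}

#' Stage 2b: cross-cohort refinement of elastic-net survivors
#'
#' Given per-cohort LASSO (alpha = 1) weight profiles, keeps the features
#' present in both cohorts' supports whose per-class weight profiles
#' correlate across cohorts above `r_threshold` (Pearson).
#'
#' @param result_a,result_b Results of [enet_multiclass()]-style fits:
#'   lists with a `weights` matrix (features x classes) and `support`.
#' @param r_threshold Inter-cohort correlation threshold (default 0.6).
#' @return Character vector of retained feature names.
#' @export
cross_cohort_refine <- function(result_a, result_b, r_threshold = 0.6) {
  common <- intersect(result_a$support, result_b$support)
  if (!length(common)) stop("empty support intersection across cohorts")
  keep <- vapply(common, function(f) {
    wa <- result_a$weights[f, ]; wb <- result_b$weights[f, ]
    if (sd(wa) == 0 || sd(wb) == 0) return(FALSE)
    cor(wa, wb) > r_threshold
  }, TRUE)
  common[keep]
}

#' Stage 3: greedy redundancy pruning
#'
#' Orders candidates by decreasing |weight| and keeps a feature only if its
#' absolute Pearson correlation with every already-kept feature stays at or
#' below `r_threshold`.
#'
#' @param values Numeric matrix of feature columns (subjects x features).
#' @param weights Named weights for the candidate columns.
#' @param r_threshold Collinearity threshold (default 0.5).
#' @return Retained feature names, in decreasing |weight| order.
#' @export
prune_redundant <- function(values, weights, r_threshold = 0.5) {
  cand <- names(sort(abs(weights), decreasing = TRUE))
  kept <- character(0)
  for (f in cand) {
    if (!length(kept)) {
      kept <- f
      next
    }
    r <- abs(cor(values[, f], values[, kept, drop = FALSE]))
    if (all(r <= r_threshold)) kept <- c(kept, f)
  }
  kept
}

#' Default selection cascade thresholds
#' @return Named list of cascade parameters.
#' @export
selection_defaults <- function() {
  list(alpha_phase1 = 0.5, alpha_phase2 = 1.0, lambda_rule = "min",
       intercohort_r = 0.6, redundancy_r = 0.5, var_threshold = 1e-8,
       ks_alpha = 0.01, k_local = 5L, k_global = 5L, folds = 10L)
}

#' Run the full three-stage feature-selection cascade
#'
#' Radiomics columns pass (1) the cross-cohort stability filter, (2) an
#' elastic-net screen at `alpha_phase1` with 10-fold CV and the minimum-MSE
#' lambda, followed by a LASSO refit (`alpha_phase2`) per cohort retaining
#' features with inter-cohort weight-profile correlation above
#' `intercohort_r`, and (3) greedy Pearson redundancy pruning at
#' `redundancy_r`. Latent dimensions of each channel are ranked by the same
#' elastic-net machinery (aggregate |weight| across one-vs-rest problems at
#' the CV-selected lambda) and the top `k_local`/`k_global` kept. With a
#' single cohort the cross-cohort rules are skipped (and logged as skipped).
#'
#' @param tables_by_cohort List of normalized radiomics `pf_feature_table`s
#'   (first = training cohort).
#' @param latents_by_cohort List per cohort of `list(local=, global=)`
#'   latent matrices (rows aligned with the tables).
#' @param labels_by_cohort List of diagnosis label vectors per cohort.
#' @param config Cascade parameters, see [selection_defaults()].
#' @param seed Integer seed (CV folds).
#' @return Object of class `pf_selection`: `radiomics`, `local`, `global`,
#'   `fused` (ordered fused column names), `weights`, `audit` (stage-wise
#'   removal record), `skipped_cross_cohort`.
#' @export
select_features <- function(tables_by_cohort, latents_by_cohort,
                            labels_by_cohort, config = selection_defaults(),
                            seed = 1L) {
  cfg <- modifyList(selection_defaults(), config)
  two <- length(tables_by_cohort) >= 2
  A <- tables_by_cohort[[1]]
  labA <- labels_by_cohort[[1]]
  audit <- list()
  # stage 1: stability
  if (two) {
    st1 <- stability_filter(A, tables_by_cohort[[2]], cfg$var_threshold,
                            cfg$ks_alpha)
    retained1 <- st1$retained
    audit$stage1 <- st1$audit
  } else {
    va <- apply(A$values, 2, var)
    retained1 <- colnames(A$values)[is.finite(va) & va >= cfg$var_threshold]
    audit$stage1 <- audit_df(setdiff(colnames(A$values), retained1),
                             "low_variance")
    message("selection: single-cohort mode, cross-cohort rules skipped")
  }
  # stage 2a: elastic-net screen on the training cohort
  XA <- A$values[, retained1, drop = FALSE]
  ph1 <- enet_multiclass(XA, labA, cfg$alpha_phase1, cfg$folds, seed)
  retained2a <- ph1$support
  audit$stage2_screen <- audit_df(setdiff(retained1, retained2a),
                                  "enet_zero")
  # stage 2b: LASSO refit per cohort + inter-cohort weight correlation
  if (two && length(retained2a)) {
    fitA <- enet_multiclass(XA[, retained2a, drop = FALSE], labA,
                            cfg$alpha_phase2, cfg$folds, seed + 100L)
    B <- tables_by_cohort[[2]]
    fitB <- enet_multiclass(B$values[, retained2a, drop = FALSE],
                            labels_by_cohort[[2]], cfg$alpha_phase2,
                            cfg$folds, seed + 200L)
    retained2 <- cross_cohort_refine(fitA, fitB, cfg$intercohort_r)
    weights <- rowSums(abs(fitA$weights[retained2, , drop = FALSE]))
  } else {
    retained2 <- retained2a
    weights <- rowSums(abs(ph1$weights[retained2, , drop = FALSE]))
  }
  audit$stage2_crosscohort <- audit_df(setdiff(retained2a, retained2),
                                       "intercohort_r")
  # stage 3: redundancy pruning
  radiomics <- if (length(retained2))
    prune_redundant(A$values[, retained2, drop = FALSE], weights,
                    cfg$redundancy_r) else character(0)
  audit$stage3 <- audit_df(setdiff(retained2, radiomics), "redundant")
  # latent ranking per channel
  rank_latents <- function(mat, k) {
    mat <- scale(mat)
    mat[, !is.finite(colSums(mat))] <- 0
    fit <- enet_multiclass(mat, labA, cfg$alpha_phase1, cfg$folds,
                           seed + 300L)
    score <- rowSums(abs(fit$weights))
    if (sum(score > 0) < k)
      warning("fewer informative latent dimensions than requested k")
    names(sort(score, decreasing = TRUE))[seq_len(min(k, length(score)))]
  }
  loc <- rank_latents(latents_by_cohort[[1]]$local, cfg$k_local)
  glo <- rank_latents(latents_by_cohort[[1]]$global, cfg$k_global)
  structure(list(radiomics = radiomics, local = loc, global = glo,
                 fused = c(radiomics, loc, glo),
                 weights = weights[radiomics], audit = audit,
                 n_input = ncol(A$values),
                 skipped_cross_cohort = !two),
            class = "pf_selection")
}

#' @export
print.pf_selection <- function(x, ...) {
  cat(sprintf(
    "<pf_selection> %d radiomics + %d local + %d global of %d candidates\n",
    length(x$radiomics), length(x$local), length(x$global), x$n_input))
  invisible(x)
}

#' Synthetic planted-signal feature tables
#'
#' Tabular benchmark for the selection cascade: `p` standard-normal feature
#' columns of which the first `n_informative` carry class-dependent mean
#' shifts, scaled by `effect`. The shift patterns are spread at equal
#' angles in the zero-sum plane of the three class means, so planted
#' features are pairwise weakly correlated and carry distinct signals. Two
#' cohorts share the planted structure; the second gets an independent
#' sample. Used to measure cascade recovery and false-discovery behaviour.
#'
#' @param n_per_class Subjects per class and cohort.
#' @param p Total feature columns.
#' @param n_informative Number of planted informative columns.
#' @param effect Mean-shift magnitude in SD units.
#' @param seed Integer seed.
#' @param n_cohorts Number of cohorts (default 2).
#' @return List: `tables` (list of `pf_feature_table`), `labels` (list),
#'   `informative` (column names of planted features).
#' @export
simulate_feature_tables <- function(n_per_class = 40, p = 50,
                                    n_informative = 5, effect = 1.0,
                                    seed = 1L, n_cohorts = 2L) {
  set.seed(as.integer(seed))
  classes <- c("IPD", "MSA", "PSP")
  cols <- sprintf("feat_%03d", seq_len(p))
  shift <- matrix(0, 3, p)
  if (n_informative > 0) {
    e1 <- c(1, -1, 0) / sqrt(2)
    e2 <- c(1, 1, -2) / sqrt(6)
    for (j in seq_len(n_informative)) {
      a <- 2 * pi * (j - 1) / n_informative
      shift[, j] <- sqrt(2) * effect * (cos(a) * e1 + sin(a) * e2)
    }
  }
  out <- lapply(seq_len(n_cohorts), function(ci) {
    lab <- rep(classes, each = n_per_class)
    X <- matrix(rnorm(length(lab) * p), length(lab), p,
                dimnames = list(NULL, cols))
    for (k in 1:3)
      X[lab == classes[k], ] <- sweep(X[lab == classes[k], , drop = FALSE],
                                      2, shift[k, ], `+`)
    list(table = feature_table(X, lab, sprintf("sim%d", ci)), labels = lab)
  })
  list(tables = lapply(out, `[[`, "table"),
       labels = lapply(out, `[[`, "labels"),
       informative = cols[seq_len(n_informative)])
}
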