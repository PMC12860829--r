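#' Gradient-boosted classifier specification
#'
#' Multiclass softmax gradient boosting with the study's hyperparameters:
#' learning rate 0.025, gamma 0.1, maximum depth 6, L2 lambda 2. Boosting
#' runs for up to `nrounds` rounds with early stopping on a seeded
#' validation fold. Probabilities come from the soft-probability variant of
#' the softmax objective.
#'
#' @param learning_rate Shrinkage per round (> 0).
#' @param gamma Minimum split loss.
#' @param max_depth Maximum tree depth (>= 1).
#' @param lambda L2 regularization on leaf weights.
#' @param nrounds Maximum boosting rounds (default 200).
#' @param early_stopping_rounds Stop if the validation loss has not improved
#'   for this many rounds (0 disables early stopping).
#' @param val_fraction Validation fraction for early stopping.
#' @param seed Integer seed.
#' @return Object of class `pf_classifier_spec`.
#' @export
classifier_spec <- function(learning_rate = 0.025, gamma = 0.1,
                            max_depth = 6, lambda = 2, nrounds = 200L,
                            early_stopping_rounds = 20L,
                            val_fraction = 0.15, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (max_depth < 1) stop("max_depth must be >= 1")
  structure(list(learning_rate = learning_rate, gamma = gamma,
                 max_depth = max_depth, lambda = lambda,
                 nrounds = as.integer(nrounds),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "pf_classifier_spec")
}

#' Fuse selected radiomics and latent features into one matrix
#'
#' Column-wise concatenation in specification order: radiomics, then local,
#' then global latents. Latent blocks are z-scored against training-cohort
#' statistics (supplied via `norm_stats`, or computed from this matrix when
#' it is the training cohort).
#'
#' @param selection A [select_features()] result (or a list with
#'   `radiomics`, `local`, `global` name vectors).
#' @param radiomics_values Normalized radiomics matrix (subjects x columns).
#' @param local_latents,global_latents Latent matrices with named columns.
#' @param norm_stats Optional latent normalization statistics from the
#'   training cohort (as returned in `$norm_stats`).
#' @return List of class `pf_fused`: `matrix`, `spec` (column order),
#'   `norm_stats`.
#' @export
fuse_features <- function(selection, radiomics_values, local_latents,
                          global_latents, norm_stats = NULL) {
  pick <- function(mat, cols, what) {
    if (!length(cols)) return(NULL)
    if (!all(cols %in% colnames(mat)))
      stop("missing ", what, " columns: ",
           paste(setdiff(cols, colnames(mat)), collapse = ", "))
    mat[, cols, drop = FALSE]
  }
  rad <- pick(radiomics_values, selection$radiomics, "radiomics")
  loc <- pick(local_latents, selection$local, "local latent")
  glo <- pick(global_latents, selection$global, "global latent")
  ns <- function(m) list(mu = colMeans(m), sd = apply(m, 2, sd))
  if (is.null(norm_stats)) {
    norm_stats <- list(local = if (!is.null(loc)) ns(loc),
                       global = if (!is.null(glo)) ns(glo))
  }
  zs <- function(m, s) {
    if (is.null(m)) return(NULL)
    sdv <- ifelse(s$sd > 0, s$sd, 1)
    sweep(sweep(m, 2, s$mu), 2, sdv, `/`)
  }
  fused <- cbind(rad, zs(loc, norm_stats$local), zs(glo, norm_stats$global))
  rows_of <- function(m) if (is.null(m)) NULL else nrow(m)
  n <- unique(unlist(lapply(list(rad, loc, glo), rows_of)))
  if (length(n) != 1) stop("subject mismatch across feature blocks")
  if (any(!is.finite(fused))) stop("missing values in fused matrix")
  structure(list(matrix = fused, spec = colnames(fused),
                 norm_stats = norm_stats),
            class = "pf_fused")
}

#' Train the multiclass gradient-boosted fusion classifier
#'
#' @param matrix Numeric feature matrix (subjects x fused features).
#' @param labels Character/factor class labels.
#' @param spec A [classifier_spec()].
#' @return Object of class `pf_classifier` wrapping the fitted booster with
#'   its feature and class vocabulary.
#' @export
train_classifier <- function(matrix, labels, spec = classifier_spec()) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(!is.finite(matrix))) stop("NaN/Inf in feature matrix")
  y <- match(labels, classes) - 1L
  params <- list(objective = "multi:softprob", num_class = length(classes),
                 eta = spec$learning_rate, gamma = spec$gamma,
                 max_depth = spec$max_depth, lambda = spec$lambda,
                 nthread = 1)
  set.seed(spec$seed)
  n <- nrow(matrix)
  use_es <- spec$early_stopping_rounds > 0 &&
    floor(spec$val_fraction * n) >= length(classes) * 2
  if (use_es) {
    val <- sample(n, floor(spec$val_fraction * n))
    if (length(unique(y[val])) < length(classes) ||
        length(unique(y[-val])) < length(classes)) use_es <- FALSE
  }
  if (use_es) {
    dtrain <- xgboost::xgb.DMatrix(matrix[-val, , drop = FALSE],
                                   label = y[-val])
    dval <- xgboost::xgb.DMatrix(matrix[val, , drop = FALSE],
                                 label = y[val])
    fit <- xgboost::xgb.train(params, dtrain, nrounds = spec$nrounds,
                              evals = list(val = dval),
                              early_stopping_rounds =
                                spec$early_stopping_rounds,
                              verbose = 0)
  } else {
    dtrain <- xgboost::xgb.DMatrix(matrix, label = y)
    fit <- xgboost::xgb.train(params, dtrain, nrounds = spec$nrounds,
                              verbose = 0)
  }
  structure(list(booster = fit, classes = classes,
                 features = colnames(matrix), spec = spec),
            class = "pf_classifier")
}

#' Predict class probabilities
#'
#' @param model A [train_classifier()] result.
#' @param matrix Feature matrix with the training columns.
#' @return Matrix of per-class probabilities (rows sum to 1), columns named
#'   by class.
#' @export
predict_proba <- function(model, matrix) {
  if (!is.null(colnames(matrix)) &&
      !identical(colnames(matrix), model$features)) {
    if (!all(model$features %in% colnames(matrix)))
      stop("feature columns do not match the training specification")
    matrix <- matrix[, model$features, drop = FALSE]
  }
  p <- predict(model$booster, xgboost::xgb.DMatrix(matrix))
  if (is.null(dim(p))) p <- matrix(p, nrow = nrow(matrix), byrow = TRUE)
  colnames(p) <- model$classes
  p
}

#' Hard class predictions
#' @inheritParams predict_proba
#' @return Character vector of predicted classes.
#' @export
predict_class <- function(model, matrix) {
  p <- predict_proba(model, matrix)
  model$classes[max.col(p, ties.method = "first")]
}

# Rank-based (trapezoidal) ROC AUC for a binary problem.
binary_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier with the multiclass metric suite
#'
#' Confusion matrix, accuracy, per-class and macro one-vs-rest AUC
#' (trapezoidal), and macro-averaged recall, precision, and F1.
#'
#' @param model A `pf_classifier`.
#' @param matrix Feature matrix.
#' @param labels True class labels.
#' @return Object of class `pf_metrics`.
#' @export
evaluate <- function(model, matrix, labels) {
  labels <- as.character(labels)
  if (!all(labels %in% model$classes)) stop("unknown label in evaluation set")
  p <- predict_proba(model, matrix)
  metrics_from_scores(p, labels, model$classes)
}

# Metric suite from a probability matrix; shared by evaluate() and tests.
metrics_from_scores <- function(p, labels, classes) {
  pred <- classes[max.col(p, ties.method = "first")]
  cm <- table(factor(labels, classes), factor(pred, classes))
  acc <- sum(diag(cm)) / sum(cm)
  per_class <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    rec <- tp / sum(cm[cl, ])
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    f1 <- if (rec + prec > 0) 2 * rec * prec / (rec + prec) else 0
    auc <- binary_auc(p[, cl], labels == cl)
    c(recall = rec, precision = prec, f1 = f1, auc = auc)
  })
  pc <- do.call(rbind, per_class)
  rownames(pc) <- classes
  structure(list(confusion = unclass(cm), accuracy = acc,
                 per_class = pc,
                 macro_auc = mean(pc[, "auc"], na.rm = TRUE),
                 macro_recall = mean(pc[, "recall"]),
                 macro_precision = mean(pc[, "precision"]),
                 macro_f1 = mean(pc[, "f1"])),
            class = "pf_metrics")
}

#' @export
print.pf_metrics <- function(x, ...) {
  cat(sprintf(
    "<pf_metrics> accuracy %.3f, macro AUC %.3f, recall %.3f, precision %.3f, F1 %.3f\n",
    x$accuracy, x$macro_auc, x$macro_recall, x$macro_precision, x$macro_f1))
  invisible(x)
}

#' Ablation comparison of feature blocks
#'
#' Trains and evaluates the classifier on radiomics-only, radiomics+local,
#' radiomics+global, and the fully fused feature sets.
#'
#' @param fused_train,fused_test `pf_fused` objects sharing a spec.
#' @param selection The [select_features()] result (defines the blocks).
#' @param labels_train,labels_test Class labels.
#' @param spec A [classifier_spec()].
#' @return Named list of `pf_metrics` for `radiomics`, `radiomics_local`,
#'   `radiomics_global`, `fused`.
#' @export
run_ablations <- function(fused_train, fused_test, selection, labels_train,
                          labels_test, spec = classifier_spec()) {
  blocks <- list(
    radiomics = selection$radiomics,
    radiomics_local = c(selection$radiomics, selection$local),
    radiomics_global = c(selection$radiomics, selection$global),
    fused = c(selection$radiomics, selection$local, selection$global))
  lapply(blocks, function(cols) {
    cols <- intersect(cols, colnames(fused_train$matrix))
    m <- train_classifier(fused_train$matrix[, cols, drop = FALSE],
                          labels_train, spec)
    evaluate(m, fused_test$matrix[, cols, drop = FALSE], labels_test)
  })
}
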