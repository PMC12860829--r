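# Shapley-value attribution for the fusion classifier, with an exact
# enumerator for small feature sets and a seeded permutation-sampling
# estimator for routine use. The value function is interventional:
# v(S) = mean model output over background rows whose features in S are
# replaced by the instance's values.

predict_fun <- function(model) {
  if (inherits(model, "pf_classifier"))
    return(function(m) predict_proba(model, m))
  if (is.function(model)) {
    return(function(m) {
      out <- model(m)
      if (is.null(dim(out))) matrix(out, nrow(m)) else as.matrix(out)
    })
  }
  stop("unsupported model type")
}

#' Exact Shapley attribution for one instance
#'
#' Enumerates all 2^F coalitions:
#' `phi_i = sum_S |S|! (F-|S|-1)! / F! (v(S u i) - v(S))` with the
#' interventional value function over a background sample. Feasible for
#' F <= 20; intended for audits and small fused models.
#'
#' @param model A `pf_classifier` or a function `matrix -> outputs`.
#' @param background Background matrix (rows = reference samples).
#' @param instance Single feature row (named numeric or 1-row matrix).
#' @return Object of class `pf_shap_single`: `phi` (features x classes),
#'   `base` (per-class background mean output), `fx` (model output on the
#'   instance).
#' @export
shapley_exact <- function(model, background, instance) {
  f <- predict_fun(model)
  x <- as.numeric(instance)
  background <- as.matrix(background)
  if (!nrow(background)) stop("background must be nonempty")
  F <- length(x)
  if (F > 20) stop("too many features for exact enumeration (F > 20)")
  B <- nrow(background)
  n_mask <- bitwShiftL(1L, F)
  # value of every coalition, evaluated in batches
  vals <- NULL
  chunk <- max(1L, floor(2e5 / B))
  v <- NULL
  for (m0 in seq(0L, n_mask - 1L, by = chunk)) {
    masks <- m0:min(n_mask - 1L, m0 + chunk - 1L)
    rows <- matrix(0, length(masks) * B, F)
    for (k in seq_along(masks)) {
      bg <- background
      on <- which(bitwAnd(bitwShiftL(1L, 0:(F - 1L)), masks[k]) != 0)
      if (length(on)) bg[, on] <- matrix(x[on], B, length(on), byrow = TRUE)
      rows[((k - 1) * B + 1):(k * B), ] <- bg
    }
    colnames(rows) <- colnames(background)
    pr <- f(rows)
    grp <- rep(seq_along(masks), each = B)
    vm <- rowsum(pr, grp) / B
    v <- rbind(v, vm)
  }
  C <- ncol(v)
  fact <- factorial(0:F)
  w <- fact[1:F] * fact[F:1] / fact[F + 1]  # |S|! (F-|S|-1)! / F!
  phi <- matrix(0, F, C)
  sizes <- vapply(0:(n_mask - 1L), function(m) sum(bitwAnd(
    bitwShiftL(1L, 0:(F - 1L)), m) != 0), 0L)
  for (i in seq_len(F)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(n_mask - 1L), bit) == 0L)
    s <- sizes[without]
    phi[i, ] <- colSums(w[s + 1L] *
                          (v[without + bit, , drop = FALSE] -
                             v[without, , drop = FALSE]))
  }
  rownames(phi) <- colnames(background)
  structure(list(phi = phi, base = unname(v[1, ]), fx = unname(v[n_mask, ])),
            class = "pf_shap_single")
}

#' Permutation-sampling Shapley estimator
#'
#' Averages marginal contributions over seeded random feature orderings;
#' reports Monte-Carlo standard errors and enforces the efficiency axiom by
#' spreading the (small) residual equally over features.
#'
#' @inheritParams shapley_exact
#' @param n_permutations Number of sampled orderings (>= 1).
#' @param seed Integer seed.
#' @return `pf_shap_single` with an additional `se` matrix.
#' @export
shapley_sampled <- function(model, background, instance, n_permutations = 200L,
                            seed = 1L) {
  f <- predict_fun(model)
  x <- as.numeric(instance)
  background <- as.matrix(background)
  if (!nrow(background)) stop("background must be nonempty")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  F <- length(x)
  B <- nrow(background)
  set.seed(as.integer(seed))
  perms <- replicate(n_permutations, sample(F), simplify = FALSE)
  # rows: per permutation, F+1 coalition blocks of B background rows
  rows <- matrix(0, n_permutations * (F + 1) * B, F)
  r0 <- 0L
  for (p in seq_len(n_permutations)) {
    bg <- background
    rows[(r0 + 1):(r0 + B), ] <- bg
    r0 <- r0 + B
    for (k in seq_len(F)) {
      j <- perms[[p]][k]
      bg[, j] <- x[j]
      rows[(r0 + 1):(r0 + B), ] <- bg
      r0 <- r0 + B
    }
  }
  colnames(rows) <- colnames(background)
  pr <- f(rows)
  C <- ncol(pr)
  grp <- rep(seq_len(n_permutations * (F + 1)), each = B)
  v <- rowsum(pr, grp) / B  # coalition values in permutation order
  contrib <- array(0, c(n_permutations, F, C))
  for (p in seq_len(n_permutations)) {
    block <- ((p - 1) * (F + 1) + 1):(p * (F + 1))
    dv <- v[block[-1], , drop = FALSE] - v[block[-(F + 1)], , drop = FALSE]
    contrib[p, perms[[p]], ] <- dv
  }
  phi <- apply(contrib, c(2, 3), mean)
  se <- apply(contrib, c(2, 3), function(z)
    sd(z) / sqrt(length(z)))
  base <- unname(colMeans(v[seq(1, nrow(v), by = F + 1), , drop = FALSE]))
  fx <- unname(colMeans(v[seq(F + 1, nrow(v), by = F + 1), , drop = FALSE]))
  resid <- fx - base - colSums(phi)
  phi <- phi + matrix(resid / F, F, C, byrow = TRUE)
  rownames(phi) <- colnames(background)
  rownames(se) <- colnames(background)
  structure(list(phi = phi, base = base, fx = fx, se = se),
            class = "pf_shap_single")
}

#' Shapley attributions for a set of instances
#'
#' Applies the sampled (default) or exact estimator to each row and stacks
#' the results into a per-class attribution array.
#'
#' @param model A `pf_classifier` or prediction function.
#' @param background Background matrix.
#' @param instances Matrix of instances (rows).
#' @param method `"sampled"` or `"exact"`.
#' @param n_permutations Permutations per instance for the sampled
#'   estimator.
#' @param seed Integer seed.
#' @return Object of class `pf_shap`: `phi` (instances x features x
#'   classes), `base`, `features`, `classes`.
#' @export
shap_matrix <- function(model, background, instances, method = "sampled",
                        n_permutations = 60L, seed = 1L) {
  method <- match.arg(method, c("sampled", "exact"))
  instances <- as.matrix(instances)
  n <- nrow(instances)
  classes <- if (inherits(model, "pf_classifier")) model$classes else NULL
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- if (method == "exact")
      shapley_exact(model, background, instances[i, ])
    else shapley_sampled(model, background, instances[i, ], n_permutations,
                         seed + i)
  }
  F <- ncol(instances)
  C <- length(res[[1]]$base)
  phi <- array(0, c(n, F, C))
  for (i in seq_len(n)) phi[i, , ] <- res[[i]]$phi
  if (is.null(classes)) classes <- paste0("class", seq_len(C))
  structure(list(phi = phi, base = res[[1]]$base,
                 features = colnames(instances), classes = classes),
            class = "pf_shap")
}

#' Mean-absolute-attribution importance profile
#'
#' @param shap A `pf_shap` (or single-instance `pf_shap_single`).
#' @return Object of class `pf_importance`: matrix features x classes of
#'   mean |phi|, plus per-class descending rank order.
#' @export
importance_profile <- function(shap) {
  if (inherits(shap, "pf_shap_single"))
    imp <- abs(shap$phi)
  else
    imp <- apply(abs(shap$phi), c(2, 3), mean)
  if (inherits(shap, "pf_shap")) {
    rownames(imp) <- shap$features
    colnames(imp) <- shap$classes
  }
  structure(list(importance = imp,
                 ranking = apply(imp, 2, function(v)
                   rownames(imp)[order(v, decreasing = TRUE)],
                   simplify = FALSE)),
            class = "pf_importance")
}

#' Cross-cohort concordance of importance profiles
#'
#' Pearson correlation (with two-sided p-value) of the per-class
#' mean-|phi| vectors of two cohorts over their shared feature universe.
#'
#' @param profile_a,profile_b `pf_importance` objects.
#' @return Data frame with `class`, `r`, `p`.
#' @export
cohort_concordance <- function(profile_a, profile_b) {
  A <- profile_a$importance; B <- profile_b$importance
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) < 3) stop("fewer than 3 shared features")
  out <- lapply(colnames(A), function(cl) {
    ct <- cor.test(A[shared, cl], B[shared, cl])
    data.frame(class = cl, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}

#' Group-average attribution map
#'
#' Voxelwise mean of subject-level attribution maps, renormalized to [0,1];
#' the group-level summary used to compare saliency across diagnoses.
#'
#' @param maps List of `pf_attribution` maps sharing geometry.
#' @param class Label recorded on the output (default from first map).
#' @return A `pf_attribution`.
#' @export
group_average_map <- function(maps, class = NULL) {
  if (!length(maps)) stop("empty map list")
  d <- dim(maps[[1]]$data)
  acc <- array(0, d)
  for (m in maps) {
    if (!identical(dim(m$data), d)) stop("attribution geometry mismatch")
    acc <- acc + m$data
  }
  acc <- acc / length(maps)
  attribution_volume(acc, maps[[1]]$spacing,
                     class %||% maps[[1]]$class %||% "group",
                     maps[[1]]$source %||% "group")
}

#' Mean attribution contrast between planted and unaffected regions
#'
#' Summarizes an attribution map against the atlas: the mean map value
#' inside the given effect regions divided by the mean over reference
#' regions (by default all other labelled regions; the pipeline passes the
#' regions left unaffected in every syndrome). Values > 1 mean the map
#' ranks the effect regions higher.
#'
#' @param map A `pf_attribution` in atlas geometry.
#' @param atlas A `pf_atlas`.
#' @param regions Region names with planted effects.
#' @param reference Optional reference region names (default: all labelled
#'   regions not in `regions`).
#' @return Named list: `inside`, `outside`, `ratio`.
#' @export
attribution_region_contrast <- function(map, atlas, regions,
                                        reference = NULL) {
  ids <- match(regions, atlas$registry)
  if (any(is.na(ids))) stop("unknown region name")
  m <- map$data
  if (!identical(dim(m), dim(atlas$labels)))
    stop("map geometry mismatches atlas")
  sel_in <- atlas$labels %in% ids
  if (is.null(reference)) {
    sel_out <- atlas$labels > 0 & !sel_in
  } else {
    rids <- match(setdiff(reference, regions), atlas$registry)
    if (any(is.na(rids))) stop("unknown region name")
    sel_out <- atlas$labels %in% rids
  }
  inside <- mean(m[sel_in]); outside <- mean(m[sel_out])
  list(inside = inside, outside = outside,
       ratio = if (outside > 0) inside / outside else Inf)
}
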