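# End-to-end pipeline orchestration: phantom cohorts -> preprocessing ->
# radiomics + dual-channel latents -> selection cascade -> fused boosted
# classifier -> interpretability (SHAP, Layer-CAM, rollout) -> report.

subset_table <- function(table, idx) {
  out <- table
  out$values <- table$values[idx, , drop = FALSE]
  out$subjects <- table$subjects[idx]
  out$diagnosis <- table$diagnosis[idx]
  out
}

# Stratified head split: first n_train of each class are training subjects.
split_cohort <- function(diagnosis, n_train_per_class) {
  tr <- unlist(lapply(unique(diagnosis), function(cl) {
    head(which(diagnosis == cl), n_train_per_class)
  }))
  sort(tr)
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[petfusion] ", fmt), ...))
}

#' Run the full desk-scale pipeline
#'
#' Executes every stage on two seeded phantom cohorts (a training-center
#' cohort and an external cohort with shifted nuisance parameters):
#' simulation, SUVR + z-score preprocessing, radiomics extraction, training
#' of the local and global channels, latent extraction, the three-stage
#' selection cascade, fused gradient-boosted classification with blind-test
#' and external evaluation, SHAP importance concordance across cohorts, and
#' group-average attribution maps scored against the planted effect
#' regions. Deterministic given `config$seed`.
#'
#' @param config A (partial) configuration; see [default_config()].
#' @param verbose Log stage progress and feature counts.
#' @return Object of class `pf_report`.
#' @export
run_pipeline <- function(config = list(), verbose = TRUE) {
  cfg <- if (inherits(config, "pf_config")) config else
    validate_config(config)
  t_start <- Sys.time()
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 20)
  ph <- cfg$phantom
  n_total <- ph$n_train_per_class + ph$n_test_per_class
  atlas <- build_parcellation(ph$grid_shape, ph$spacing, ph$atlas_seed)

  stage_log(verbose, "phantom: simulating cohorts (%d + %d subjects)",
            3 * n_total, if (ph$two_cohorts) 3 * n_total else 0)
  specA <- phantom_spec(c(IPD = n_total, MSA = n_total, PSP = n_total),
                        effects = default_effect_table(ph$noise_sd),
                        grid_shape = ph$grid_shape, spacing = ph$spacing,
                        fwhm_mm = ph$fwhm_mm, atlas_seed = ph$atlas_seed,
                        cohort_id = "cohortA")
  cohorts <- list(A = simulate_cohort(specA, seeds[1], atlas))
  if (ph$two_cohorts) {
    specB <- phantom_spec_external(
      c(IPD = n_total, MSA = n_total, PSP = n_total),
      grid_shape = ph$grid_shape, spacing = ph$spacing,
      fwhm_mm = ph$fwhm_mm, atlas_seed = ph$atlas_seed,
      cohort_id = "cohortB")
    cohorts$B <- simulate_cohort(specB, seeds[2], atlas)
  }

  stage_log(verbose, "radiomics: extracting feature tables")
  tabs <- lapply(cohorts, function(co)
    extract_table(co, atlas, cfg$radiomics$families, cfg$radiomics$bin_width))
  n_candidates <- ncol(tabs$A$values)
  stage_log(verbose, "radiomics: %d candidate columns per cohort",
            n_candidates)

  diagA <- tabs$A$diagnosis
  trA <- split_cohort(diagA, ph$n_train_per_class)
  teA <- setdiff(seq_along(diagA), trA)
  refA <- subset_table(tabs$A, trA)
  normA <- normalize_table(tabs$A, refA)
  norm_tabs <- list(A = normA)
  if (ph$two_cohorts) {
    # external cohort normalized against its own training split, mirroring
    # per-center feature standardization
    diagB <- tabs$B$diagnosis
    trB <- split_cohort(diagB, ph$n_train_per_class)
    teB <- setdiff(seq_along(diagB), trB)
    norm_tabs$B <- normalize_table(tabs$B, subset_table(tabs$B, trB))
    shared <- intersect(colnames(norm_tabs$A$values),
                        colnames(norm_tabs$B$values))
    for (k in names(norm_tabs))
      norm_tabs[[k]]$values <- norm_tabs[[k]]$values[, shared, drop = FALSE]
  }

  stage_log(verbose, "preprocess: z-scored SUVR volumes for the channels")
  zvols <- lapply(cohorts, function(co)
    lapply(co$subjects, function(s) zscore_image(to_suvr(s$volume))))

  stage_log(verbose, "localnet: training dilated-convolution channel")
  classes <- sort(unique(diagA))
  lshape <- cfg$localnet$input_shape %||% ph$grid_shape
  zloc <- lapply(zvols, function(vs) lapply(vs, function(v)
    if (identical(dim(v$data), as.integer(lshape))) v
    else resize_volume(v, lshape)))
  lcfg <- local_net_config(lshape, cfg$localnet$filters,
                           cfg$localnet$dilations, classes)
  net_idx <- unlist(lapply(classes, function(cl)
    head(intersect(trA, which(diagA == cl)),
         cfg$localnet$n_net_train_per_class)))
  lnet <- build_local_encoder(lcfg, seeds[3])
  lnet <- train_network(lnet, zloc$A[net_idx], diagA[net_idx],
                        list(epochs = cfg$localnet$epochs,
                             lr = cfg$localnet$lr,
                             batch_size = cfg$localnet$batch_size,
                             seed = seeds[4]))

  stage_log(verbose, "globalnet: training Transformer channel")
  gcfg <- global_net_config(cfg$globalnet$input_shape,
                            cfg$globalnet$patch_kernel,
                            cfg$globalnet$patch_stride,
                            cfg$globalnet$embed_dim, cfg$globalnet$depth,
                            cfg$globalnet$heads, cfg$globalnet$latent_dim,
                            classes = classes)
  zglo <- lapply(zvols, function(vs) lapply(vs, function(v)
    if (identical(dim(v$data), gcfg$input_shape)) v
    else resize_volume(v, gcfg$input_shape)))
  gnet <- build_global_encoder(gcfg, seeds[5])
  gnet <- train_network(gnet, zglo$A[net_idx], diagA[net_idx],
                        list(epochs = cfg$globalnet$epochs,
                             lr = cfg$globalnet$lr,
                             batch_size = cfg$globalnet$batch_size,
                             seed = seeds[6]))

  stage_log(verbose, "latents: extracting dual-channel features")
  latents <- Map(function(vl, vg) list(
    local = t(vapply(vl, function(v) extract_local_latents(lnet, v),
                     numeric(lcfg$latent_dim))),
    global = t(vapply(vg, function(v) extract_global_latents(gnet, v),
                      numeric(gcfg$latent_dim)))), zloc, zglo)

  stage_log(verbose, "selection: three-stage cascade on %d candidates",
            ncol(norm_tabs$A$values))
  tables_sel <- list(subset_table(norm_tabs$A, trA))
  latents_sel <- list(lapply(latents$A, function(m)
    m[trA, , drop = FALSE]))
  labels_sel <- list(diagA[trA])
  if (ph$two_cohorts) {
    tables_sel$B <- subset_table(norm_tabs$B, trB)
    latents_sel$B <- lapply(latents$B, function(m) m[trB, , drop = FALSE])
    labels_sel$B <- diagB[trB]
  }
  sel <- select_features(tables_sel, latents_sel, labels_sel,
                         cfg$selection, seeds[7])
  stage_log(verbose, "selection: %d radiomics + %d local + %d global",
            length(sel$radiomics), length(sel$local), length(sel$global))

  stage_log(verbose, "fusion: training boosted classifier")
  cspec <- classifier_spec(cfg$classifier$learning_rate, cfg$classifier$gamma,
                           cfg$classifier$max_depth, cfg$classifier$lambda,
                           cfg$classifier$nrounds, seed = seeds[8])
  fuse_of <- function(cohort_key, idx) {
    fuse_features(sel,
                  norm_tabs[[cohort_key]]$values[idx, , drop = FALSE],
                  latents[[cohort_key]]$local[idx, , drop = FALSE],
                  latents[[cohort_key]]$global[idx, , drop = FALSE],
                  norm_stats = train_stats)
  }
  train_stats <- NULL
  fused_train <- fuse_of("A", trA)
  train_stats <- fused_train$norm_stats
  fused_testA <- fuse_of("A", teA)
  model <- train_classifier(fused_train$matrix, diagA[trA], cspec)
  metrics <- list(blind_test = evaluate(model, fused_testA$matrix,
                                        diagA[teA]))
  if (ph$two_cohorts) {
    fused_testB <- fuse_of("B", teB)
    metrics$external <- evaluate(model, fused_testB$matrix, diagB[teB])
  }
  ablation <- NULL
  if (isTRUE(cfg$classifier$ablations))
    ablation <- run_ablations(fused_train, fused_testA, sel, diagA[trA],
                              diagA[teA], cspec)

  stage_log(verbose, "interpret: SHAP attribution and concordance")
  set.seed(seeds[9])
  bg_idx <- sample(nrow(fused_train$matrix),
                   min(cfg$interpret$background_n, nrow(fused_train$matrix)))
  background <- fused_train$matrix[bg_idx, , drop = FALSE]
  take_instances <- function(m) {
    if (nrow(m) <= cfg$interpret$instances_max) return(seq_len(nrow(m)))
    sort(sample(nrow(m), cfg$interpret$instances_max))
  }
  set.seed(seeds[10])
  iA <- take_instances(fused_testA$matrix)
  shapA <- shap_matrix(model, background, fused_testA$matrix[iA, ,
                                                             drop = FALSE],
                       n_permutations = cfg$interpret$n_permutations,
                       seed = seeds[11])
  profA <- importance_profile(shapA)
  concordance <- NULL
  if (ph$two_cohorts) {
    set.seed(seeds[12])
    iB <- take_instances(fused_testB$matrix)
    shapB <- shap_matrix(model, background,
                         fused_testB$matrix[iB, , drop = FALSE],
                         n_permutations = cfg$interpret$n_permutations,
                         seed = seeds[13])
    concordance <- cohort_concordance(profA, importance_profile(shapB))
  }

  stage_log(verbose, "attribution: group-average Layer-CAM and rollout maps")
  effectsA <- specA$effects
  planted <- lapply(effectsA[c("MSA", "PSP")], function(e)
    names(e$factors)[e$factors != 1])

  attr_contrast <- list()
  group_maps <- list()
  for (cl in c("MSA", "PSP")) {
    idx <- head(intersect(teA, which(diagA == cl)),
                cfg$attribution$n_subjects)
    cams <- lapply(idx, function(i) {
      cam <- layer_cam(lnet, zloc$A[[i]], cl)
      if (!identical(dim(cam$data), dim(atlas$labels)))
        cam <- attribution_volume(
          pmax(resize_trilinear(cam$data, dim(atlas$labels)), 0),
          ph$spacing, cl, "layer_cam")
      cam
    })
    rolls <- lapply(idx, function(i) rollout_map(gnet, zvols$A[[i]]))
    gcam <- group_average_map(cams, cl)
    groll <- group_average_map(rolls, cl)
    group_maps[[cl]] <- list(layer_cam = gcam, rollout = groll)
    attr_contrast[[cl]] <- list(
      layer_cam = attribution_region_contrast(gcam, atlas, planted[[cl]]),
      rollout = attribution_region_contrast(groll, atlas, planted[[cl]]))
  }

  elapsed <- as.numeric(Sys.time() - t_start, units = "secs")
  stage_log(verbose, "done in %.1f s", elapsed)
  structure(list(
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    n_candidates = n_candidates,
    n_after_stability = ncol(norm_tabs$A$values) -
      nrow(sel$audit$stage1),
    selection = list(radiomics = sel$radiomics, local = sel$local,
                     global = sel$global, fused = sel$fused),
    fused_width = length(sel$fused),
    metrics = metrics,
    ablation = ablation,
    concordance = concordance,
    attribution = attr_contrast,
    group_maps = group_maps,
    planted_regions = planted,
    training = list(local_log = lnet$log, global_log = gnet$log),
    elapsed_sec = elapsed),
    class = "pf_report")
}

#' @export
print.pf_report <- function(x, ...) {
  cat(sprintf("<pf_report> seed %d: %d candidates -> %d fused features\n",
              x$seed, x$n_candidates, x$fused_width))
  cat(sprintf("  blind-test: acc %.3f, macro AUC %.3f\n",
              x$metrics$blind_test$accuracy, x$metrics$blind_test$macro_auc))
  if (!is.null(x$metrics$external))
    cat(sprintf("  external:   acc %.3f, macro AUC %.3f\n",
                x$metrics$external$accuracy, x$metrics$external$macro_auc))
  if (!is.null(x$concordance))
    cat(sprintf("  SHAP concordance r: %s\n",
                paste(sprintf("%s %.2f", x$concordance$class,
                              x$concordance$r), collapse = ", ")))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Attribution volumes are summarized by their region contrasts (the full
#' maps can be written separately as NIfTI); everything else round-trips.
#'
#' @param report A `pf_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$group_maps <- NULL
  out$metrics <- lapply(out$metrics, unclass)
  out$ablation <- if (!is.null(out$ablation)) lapply(out$ablation, unclass)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", force = TRUE), path)
  invisible(path)
}
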