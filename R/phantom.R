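#' Disease effect specification
#'
#' A diagnosis label together with multiplicative regional uptake factors
#' (1 = unaffected) and the voxelwise multiplicative noise standard
#' deviation applied before smoothing.
#'
#' @param label One of `"HC"`, `"IPD"`, `"MSA"`, `"PSP"`.
#' @param factors Named numeric vector, region name -> factor (> 0). Regions
#'   not named keep factor 1.
#' @param noise_sd Voxel noise sd as a fraction of the baseline.
#' @return Object of class `pf_effect`.
#' @export
disease_effect <- function(label, factors = numeric(0), noise_sd = 0.10) {
  label <- match.arg(label, c("HC", "IPD", "MSA", "PSP"))
  if (length(factors)) {
    if (is.null(names(factors)) || !all(names(factors) %in% region_names()))
      stop("factors must be named by atlas regions")
    if (any(factors <= 0)) stop("factors must be positive")
  }
  if (label == "HC" && length(factors) && any(factors != 1))
    stop("HC factors must all be 1")
  structure(list(label = label, factors = factors, noise_sd = noise_sd),
            class = "pf_effect")
}

#' Default disease effect table
#'
#' The study conditions of the phantom simulator: multiplicative regional
#' hypometabolism patterns echoing the metabolic deficits described for each
#' syndrome — MSA: putamen, pons, dentate nucleus; PSP: caudate nucleus,
#' thalamus, midbrain; IPD: mild occipital reduction with relative putaminal
#' preservation/increase. Magnitudes are simulator parameters chosen so a
#' desk-scale cohort is highly but not perfectly separable.
#'
#' @param noise_sd Voxel noise sd (default 0.10).
#' @param shrink Multiplier in (0,1] pulling effect magnitudes toward 1
#'   (used by the second-cohort generator).
#' @return Named list of [disease_effect()] objects for HC, IPD, MSA, PSP.
#' @export
default_effect_table <- function(noise_sd = 0.10, shrink = 1.0) {
  sh <- function(f) 1 + shrink * (f - 1)
  list(
    HC  = disease_effect("HC", noise_sd = noise_sd),
    IPD = disease_effect("IPD", sh(c(occipital_cortex = 0.92, putamen = 1.05)),
                         noise_sd),
    MSA = disease_effect("MSA", sh(c(putamen = 0.85, pons = 0.85,
                                     dentate_nucleus = 0.88)), noise_sd),
    PSP = disease_effect("PSP", sh(c(caudate_nucleus = 0.85, thalamus = 0.88,
                                     midbrain = 0.85)), noise_sd))
}

#' Default regional baseline uptake map
#'
#' Mean uptake per region plus the generic `"background"` tissue inside the
#' brain envelope, in arbitrary units mimicking FDG gray-matter contrast
#' (striatal structures hottest, white-matter-like background coolest).
#'
#' @return Named numeric vector over [region_names()] plus `"background"`.
#' @export
default_baseline_map <- function() {
  b <- setNames(rep(1.0, 20), region_names())
  b[c("putamen", "caudate_nucleus", "globus_pallidus", "thalamus")] <- 1.25
  b[c("nucleus_accumbens", "subthalamic_nucleus")] <- 1.15
  b[c("midbrain", "pons", "medulla_oblongata", "dentate_nucleus")] <- 1.05
  c(b, background = 0.75)
}

#' Simulate one subject's PET volume
#'
#' Voxel value = regional baseline x disease factor x (1 + Gaussian noise),
#' then Gaussian smoothing at the given FWHM. Background tissue inside the
#' brain envelope uses the `"background"` baseline with factor 1; voxels
#' outside the envelope are 0 and excluded from the mask.
#'
#' @param atlas A [build_parcellation()] atlas.
#' @param effect A [disease_effect()].
#' @param baseline_map Named baselines as in [default_baseline_map()].
#' @param seed Integer seed (fully determines the subject).
#' @param fwhm_mm Smoothing FWHM in mm (default 10).
#' @param gain Global intensity gain (cohort-level nuisance, default 1).
#' @return A [volume3d()] with mask = brain envelope.
#' @export
simulate_subject <- function(atlas, effect, baseline_map = default_baseline_map(),
                             seed = 1L, fwhm_mm = 10, gain = 1.0) {
  need <- c(region_names(), "background")
  if (!all(need %in% names(baseline_map)))
    stop("baseline_map must cover every region and 'background'")
  if (any(baseline_map[need] <= 0)) stop("baselines must be positive")
  base <- array(0, dim(atlas$labels))
  base[atlas$envelope] <- baseline_map[["background"]]
  fac <- setNames(rep(1.0, 20), region_names())
  fac[names(effect$factors)] <- effect$factors
  for (i in seq_len(20L)) {
    sel <- atlas$labels == i
    base[sel] <- baseline_map[[region_names()[i]]] * fac[[i]]
  }
  set.seed(as.integer(seed))
  noise <- array(rnorm(length(base), 0, effect$noise_sd), dim(base))
  raw <- gain * base * (1 + noise)
  raw[!atlas$envelope] <- 0
  vol <- volume3d(raw, atlas$spacing, atlas$envelope)
  gaussian_smooth(vol, fwhm_mm)
}

#' Phantom cohort specification
#'
#' @param n_per_class Named integer vector of subject counts per diagnosis,
#'   e.g. `c(IPD = 30, MSA = 30, PSP = 30)`.
#' @param effects Effect table as from [default_effect_table()].
#' @param baseline_map Regional baselines.
#' @param grid_shape,spacing Atlas geometry.
#' @param fwhm_mm Smoothing FWHM in mm.
#' @param gain Global intensity gain.
#' @param atlas_seed Seed for the parcellation jitter.
#' @param cohort_id Cohort identifier string.
#' @return Object of class `pf_phantom_spec`.
#' @export
phantom_spec <- function(n_per_class = c(IPD = 30, MSA = 30, PSP = 30),
                         effects = default_effect_table(),
                         baseline_map = default_baseline_map(),
                         grid_shape = c(79, 95, 69), spacing = c(2, 2, 2),
                         fwhm_mm = 10, gain = 1.0, atlas_seed = 1L,
                         cohort_id = "cohortA") {
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% c("HC", "IPD", "MSA", "PSP")))
    stop("n_per_class must be named by diagnoses")
  if (any(n_per_class < 1)) stop("zero subjects requested for a class")
  structure(list(n_per_class = n_per_class, effects = effects,
                 baseline_map = baseline_map, grid_shape = grid_shape,
                 spacing = spacing, fwhm_mm = fwhm_mm, gain = gain,
                 atlas_seed = atlas_seed, cohort_id = cohort_id),
            class = "pf_phantom_spec")
}

#' Second-cohort ("external") phantom specification
#'
#' A generator with shifted nuisance parameters emulating an independent
#' center: global gain x1.1, noise sd 0.12, and effect magnitudes shrunk by
#' 10%, while sharing the disease effect structure. Exercises the
#' cross-cohort stability machinery.
#'
#' @inheritParams phantom_spec
#' @return A [phantom_spec()] with shifted nuisance parameters.
#' @export
phantom_spec_external <- function(n_per_class = c(IPD = 30, MSA = 30, PSP = 30),
                                  grid_shape = c(79, 95, 69),
                                  spacing = c(2, 2, 2), fwhm_mm = 10,
                                  atlas_seed = 1L, cohort_id = "cohortB") {
  phantom_spec(n_per_class,
               effects = default_effect_table(noise_sd = 0.12, shrink = 0.9),
               grid_shape = grid_shape, spacing = spacing, fwhm_mm = fwhm_mm,
               gain = 1.1, atlas_seed = atlas_seed, cohort_id = cohort_id)
}

#' Simulate a labelled phantom cohort
#'
#' Per-subject seeds are derived from the cohort seed, so the whole cohort
#' is reproducible from `(spec, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer cohort seed.
#' @param atlas Optional pre-built atlas (must match `spec` geometry).
#' @return Object of class `pf_cohort`: `subjects` (list of `id`, `volume`,
#'   `diagnosis`), `manifest` (data.frame), `atlas`, `cohort_id`, `seed`.
#' @export
simulate_cohort <- function(spec, seed = 1L, atlas = NULL) {
  if (is.null(atlas))
    atlas <- build_parcellation(spec$grid_shape, spec$spacing,
                                spec$atlas_seed)
  classes <- rep(names(spec$n_per_class), times = spec$n_per_class)
  n <- length(classes)
  set.seed(as.integer(seed))
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- simulate_subject(atlas, spec$effects[[classes[i]]],
                            spec$baseline_map, seed = subj_seeds[i],
                            fwhm_mm = spec$fwhm_mm, gain = spec$gain)
    subjects[[i]] <- list(id = sprintf("%s_s%03d", spec$cohort_id, i),
                          volume = vol, diagnosis = classes[i])
  }
  manifest <- data.frame(
    subject = vapply(subjects, `[[`, "", "id"),
    diagnosis = classes, cohort = spec$cohort_id, seed = subj_seeds,
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, manifest = manifest, atlas = atlas,
                 cohort_id = spec$cohort_id, seed = as.integer(seed)),
            class = "pf_cohort")
}

#' @export
print.pf_cohort <- function(x, ...) {
  cat(sprintf("<pf_cohort> '%s': %d subjects (%s), seed %d\n", x$cohort_id,
              nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$diagnosis)),
                            table(x$manifest$diagnosis)), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits one NIfTI per subject, the atlas labels, and a TSV manifest
#' (subject id, diagnosis, cohort, seed).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects)
    write_volume(s$volume, file.path(dir, paste0(s$id, ".nii.gz")))
  atl <- volume3d(array(as.numeric(cohort$atlas$labels),
                        dim(cohort$atlas$labels)),
                  cohort$atlas$spacing,
                  cohort$atlas$envelope)
  write_volume(atl, file.path(dir, "atlas.nii.gz"))
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
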