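#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their documented
#' defaults: the phantom study conditions, preprocessing FWHM (10 mm),
#' radiomics bin width (0.05 SUVR), the selection cascade thresholds
#' (alpha 0.5/1.0, minimum-MSE lambda, inter-cohort r 0.6, redundancy
#' r 0.5), the boosted-classifier hyperparameters (learning rate 0.025,
#' gamma 0.1, depth 6, lambda 2), and desk-scale network presets sized for a
#' single CPU. The seed is deliberately left `NULL`: every run must set it
#' explicitly.
#'
#' @return Nested list of class `pf_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = NULL,
    phantom = list(n_train_per_class = 60L, n_test_per_class = 30L,
                   grid_shape = c(32L, 36L, 32L), spacing = c(4, 4, 4),
                   fwhm_mm = 10, atlas_seed = 1L, noise_sd = 0.10,
                   two_cohorts = TRUE),
    radiomics = list(bin_width = 0.05, families = radiomics_families()),
    localnet = list(input_shape = c(16L, 18L, 16L),
                    filters = c(4L, 8L, 12L), dilations = c(1L, 2L, 3L),
                    epochs = 14L, lr = 3e-3, batch_size = 4L,
                    n_net_train_per_class = 30L),
    globalnet = list(input_shape = c(24L, 24L, 24L), patch_kernel = 6L,
                     patch_stride = 6L, embed_dim = 32L, depth = 2L,
                     heads = 4L, latent_dim = 16L, epochs = 20L, lr = 3e-3,
                     batch_size = 4L, n_net_train_per_class = 30L),
    selection = selection_defaults(),
    classifier = list(learning_rate = 0.025, gamma = 0.1, max_depth = 6L,
                      lambda = 2, nrounds = 200L, ablations = FALSE),
    interpret = list(n_permutations = 24L, background_n = 30L,
                     instances_max = 24L),
    attribution = list(n_subjects = 12L)),
    class = "pf_config")
}

config_ranges <- list(
  selection = list(alpha_phase1 = c(0, 1), alpha_phase2 = c(0, 1),
                   intercohort_r = c(0, 1), redundancy_r = c(0, 1),
                   ks_alpha = c(0, 1)),
  classifier = list(learning_rate = c(1e-6, Inf), gamma = c(0, Inf),
                    max_depth = c(1, Inf), lambda = c(0, Inf)),
  phantom = list(fwhm_mm = c(0, Inf), noise_sd = c(0, 1)),
  radiomics = list(bin_width = c(1e-9, Inf)))

#' Validate and complete a pipeline configuration
#'
#' Fills unspecified fields with the documented defaults, rejects unknown
#' keys, enforces threshold ranges, and requires an explicit seed.
#'
#' @param config Partial configuration list.
#' @return Completed `pf_config`.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  bad <- setdiff(names(config), c(names(def)))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (sec in names(config)) {
    if (sec == "seed") next
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad)) stop("unknown key(s) in [", sec, "]: ",
                          paste(bad, collapse = ", "))
  }
  cfg <- modifyList(def, config)
  if (is.null(cfg$seed)) stop("config must set an explicit seed")
  cfg$seed <- as.integer(cfg$seed)
  for (sec in names(config_ranges)) {
    for (key in names(config_ranges[[sec]])) {
      v <- cfg[[sec]][[key]]
      rng <- config_ranges[[sec]][[key]]
      if (!is.null(v) && (any(v < rng[1]) || any(v > rng[2])))
        stop(sprintf("%s.%s = %s out of range [%s, %s]", sec, key,
                     format(v), format(rng[1]), format(rng[2])))
    }
  }
  class(cfg) <- "pf_config"
  cfg
}

#' Load a pipeline configuration from JSON
#'
#' Flat JSON with one object per section (`phantom`, `radiomics`,
#' `localnet`, `globalnet`, `selection`, `classifier`, `interpret`,
#' `attribution`) plus a top-level `seed`. Unspecified fields take the
#' documented defaults; unknown keys and out-of-range thresholds are
#' errors.
#'
#' @param path Path to a JSON config file.
#' @return Validated `pf_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(raw)
}

#' Hash a configuration for provenance
#' @param config A `pf_config`.
#' @return md5 hex string of the canonical JSON encoding.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}
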