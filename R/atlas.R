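#' The 20 parcellation region names
#'
#' The cortical and subcortical regions over which radiomics features are
#' extracted: four cortical lobes plus sixteen deep gray-matter and
#' brainstem structures relevant to parkinsonian syndromes.
#'
#' @return Character vector of 20 region names, ordered by atlas label 1..20.
#' @export
region_names <- function() {
  c("frontal_cortex", "parietal_cortex", "occipital_cortex",
    "temporal_cortex", "subthalamic_nucleus", "nucleus_accumbens",
    "ventral_tegmental_area", "locus_coeruleus", "raphe_nucleus",
    "dentate_nucleus", "substantia_nigra", "red_nucleus",
    "thalamic_basal_nucleus", "caudate_nucleus", "putamen",
    "globus_pallidus", "thalamus", "medulla_oblongata", "midbrain", "pons")
}

# Fractional layout of the synthetic parcellation: centre (of grid extent)
# and ellipsoid semi-axes per region. Cortical shells sit peripherally,
# deep nuclei and brainstem structures centrally/inferiorly.
parcellation_layout <- function() {
  L <- rbind(
    frontal_cortex         = c(0.50, 0.80, 0.62, 0.27, 0.12, 0.20),
    parietal_cortex        = c(0.50, 0.40, 0.84, 0.26, 0.15, 0.11),
    occipital_cortex       = c(0.50, 0.11, 0.58, 0.23, 0.09, 0.15),
    temporal_cortex        = c(0.13, 0.52, 0.42, 0.09, 0.21, 0.13),
    subthalamic_nucleus    = c(0.60, 0.51, 0.40, 0.045, 0.045, 0.045),
    nucleus_accumbens      = c(0.42, 0.66, 0.38, 0.048, 0.048, 0.048),
    ventral_tegmental_area = c(0.50, 0.47, 0.32, 0.042, 0.042, 0.042),
    locus_coeruleus        = c(0.56, 0.30, 0.22, 0.042, 0.042, 0.042),
    raphe_nucleus          = c(0.44, 0.32, 0.24, 0.042, 0.042, 0.042),
    dentate_nucleus        = c(0.66, 0.18, 0.28, 0.055, 0.055, 0.05),
    substantia_nigra       = c(0.40, 0.46, 0.36, 0.042, 0.042, 0.042),
    red_nucleus            = c(0.57, 0.44, 0.34, 0.042, 0.042, 0.042),
    thalamic_basal_nucleus = c(0.38, 0.55, 0.52, 0.05, 0.05, 0.05),
    caudate_nucleus        = c(0.62, 0.63, 0.54, 0.055, 0.055, 0.055),
    putamen                = c(0.29, 0.58, 0.44, 0.06, 0.06, 0.055),
    globus_pallidus        = c(0.70, 0.55, 0.44, 0.05, 0.05, 0.05),
    thalamus               = c(0.50, 0.54, 0.56, 0.06, 0.06, 0.055),
    medulla_oblongata      = c(0.50, 0.30, 0.08, 0.05, 0.05, 0.045),
    midbrain               = c(0.50, 0.42, 0.42, 0.05, 0.05, 0.05),
    pons                   = c(0.50, 0.34, 0.14, 0.055, 0.055, 0.05))
  colnames(L) <- c("cx", "cy", "cz", "rx", "ry", "rz")
  L
}

#' Build the synthetic 20-region parcellation atlas
#'
#' Places 20 disjoint ellipsoidal regions at fixed fractional grid positions
#' (cortical shells peripheral, deep nuclei central), labelled 1..20 in the
#' order of [region_names()]. The seed applies a small deterministic jitter
#' (up to 1% of the grid) to region centres so different atlas realizations
#' can be generated reproducibly. Semi-axes are floored at 1.75 voxels so
#' regions stay usable on coarse grids. A whole-brain ellipsoidal envelope
#' (the scalp-stripped "brain") is recorded alongside the labels.
#'
#' @param grid_shape Integer length-3, at least 32 per axis.
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed for the centre jitter.
#' @return Object of class `pf_atlas`: `labels` (integer array, 0 =
#'   background), `registry` (label id -> region name), `envelope` (logical
#'   brain mask), `spacing`.
#' @export
build_parcellation <- function(grid_shape = c(79, 95, 69),
                               spacing = c(2, 2, 2), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L))
    stop("grid too small: need at least 32 voxels per axis")
  lay <- parcellation_layout()
  set.seed(as.integer(seed))
  jit <- matrix(runif(nrow(lay) * 3, -0.01, 0.01), ncol = 3)
  labels <- array(0L, grid_shape)
  xs <- seq_len(grid_shape[1]); ys <- seq_len(grid_shape[2])
  zs <- seq_len(grid_shape[3])
  coords <- list(
    x = rep(xs, times = grid_shape[2] * grid_shape[3]),
    y = rep(rep(ys, each = grid_shape[1]), times = grid_shape[3]),
    z = rep(zs, each = grid_shape[1] * grid_shape[2]))
  for (i in seq_len(nrow(lay))) {
    ctr <- (lay[i, 1:3] + jit[i, ]) * grid_shape
    sem <- pmax(lay[i, 4:6] * grid_shape, 1.75)
    d2 <- ((coords$x - ctr[1]) / sem[1])^2 +
          ((coords$y - ctr[2]) / sem[2])^2 +
          ((coords$z - ctr[3]) / sem[3])^2
    sel <- d2 <= 1 & labels == 0L   # earlier regions take precedence
    if (!any(sel))
      stop("grid too small to place region ", rownames(lay)[i])
    labels[sel] <- i
  }
  ctr <- grid_shape / 2
  sem <- grid_shape * c(0.47, 0.48, 0.46)
  env <- ((coords$x - ctr[1]) / sem[1])^2 + ((coords$y - ctr[2]) / sem[2])^2 +
         ((coords$z - ctr[3]) / sem[3])^2 <= 1
  envelope <- array(env, grid_shape) | labels > 0L
  structure(list(labels = labels,
                 registry = setNames(region_names(), seq_len(20L)),
                 envelope = envelope,
                 spacing = as.numeric(spacing)),
            class = "pf_atlas")
}

#' @export
print.pf_atlas <- function(x, ...) {
  cat(sprintf("<pf_atlas> %s grid, %d regions, %d envelope voxels\n",
              paste(dim(x$labels), collapse = "x"), length(x$registry),
              sum(x$envelope)))
  invisible(x)
}
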