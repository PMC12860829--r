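#' Discretize ROI intensities into gray levels
#'
#' Fixed-bin-width discretization anchored at the ROI minimum:
#' `level = floor((x - min) / bin_width) + 1`, so the maximum maps to
#' `Ng = floor((max - min) / bin_width) + 1` (`Ng = 1` for a constant ROI;
#' when the range is an exact multiple of the bin width the maximum opens
#' its own level).
#' Levels are laid out on the ROI bounding-box grid with 0 outside the ROI.
#'
#' @param volume A [volume3d()].
#' @param roi_mask Logical array, same shape as the volume.
#' @param bin_width Positive bin width on the volume's intensity scale.
#' @return Object of class `pf_discrete_roi`: `levels` (integer bounding-box
#'   grid), `dims`, `ng`, `bin_width`, `values` (raw ROI intensities),
#'   `spacing`, `n_voxels`.
#' @export
discretize <- function(volume, roi_mask, bin_width) {
  if (!any(roi_mask)) stop("empty ROI")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  idx <- which(roi_mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sub_mask <- roi_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_data <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dims <- dim(sub_mask)
  vals <- sub_data[sub_mask]
  levels_flat <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  ng <- max(levels_flat)
  lev <- array(0L, dims)
  lev[sub_mask] <- levels_flat
  structure(list(levels = lev, dims = dims, ng = ng, bin_width = bin_width,
                 values = vals, spacing = volume$spacing,
                 n_voxels = length(vals), mask = sub_mask),
            class = "pf_discrete_roi")
}

#' Compute a gray-level texture matrix
#'
#' Counts are accumulated by direct neighbourhood scan over the 13 unique 3D
#' directions at distance 1 (where directional). Conventions: the GLCM is
#' symmetrized and aggregated by summing counts over directions, then
#' normalized; GLRLM runs are maximal collinear same-level segments, summed
#' over directions; GLSZM zones are 26-connected equal-level components;
#' NGTDM uses 26-neighbourhood mean absolute differences; GLDM dependence is
#' 1 + the number of 26-neighbours within `alpha` level difference.
#'
#' @param droi A [discretize()] result.
#' @param family One of `"glcm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`, `"gldm"`.
#' @param params Optional list; `alpha` (GLDM level tolerance, default 0).
#' @return Object of class `pf_texture_matrix` with fields `family`,
#'   `counts` (family-specific axis semantics) and, for GLCM, the
#'   normalized probability matrix `P`.
#' @export
texture_matrix <- function(droi, family, params = list()) {
  family <- match.arg(family, c("glcm", "glrlm", "glszm", "ngtdm", "gldm"))
  lev <- as.integer(droi$levels)
  dims <- as.integer(droi$dims)
  ng <- droi$ng
  out <- switch(family,
    glcm = {
      counts <- cpp_glcm(lev, dims, ng)
      P <- if (sum(counts) > 0) counts / sum(counts) else counts
      list(counts = counts, P = P)
    },
    glrlm = list(counts = trim_cols(cpp_glrlm(lev, dims, ng))),
    glszm = {
      zones <- cpp_glszm_zones(lev, dims)
      maxz <- max(zones[, 2])
      m <- matrix(0, ng, maxz)
      for (k in seq_len(nrow(zones)))
        m[zones[k, 1], zones[k, 2]] <- m[zones[k, 1], zones[k, 2]] + 1
      list(counts = m)
    },
    ngtdm = {
      m <- cpp_ngtdm(lev, dims, ng)
      colnames(m) <- c("n", "s")
      list(counts = m)
    },
    gldm = {
      alpha <- if (is.null(params$alpha)) 0 else params$alpha
      list(counts = trim_cols(cpp_gldm(lev, dims, ng, alpha)))
    })
  structure(c(list(family = family, ng = ng), out),
            class = "pf_texture_matrix")
}

trim_cols <- function(m) {
  keep <- max(1L, max(which(colSums(m) > 0)))
  m[, seq_len(keep), drop = FALSE]
}
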