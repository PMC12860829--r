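#' Gaussian smoothing of a PET volume
#'
#' Separable 3D Gaussian filter parameterized by full width at half maximum
#' in millimetres, the convention PET pipelines use. Per axis,
#' `sigma_voxels = fwhm_mm / (2 * sqrt(2 * log(2))) / spacing`. Boundaries
#' are handled by mirror reflection so that interior-supported signals keep
#' their total intensity. The mask is unchanged.
#'
#' @param volume A [volume3d()].
#' @param fwhm_mm Kernel FWHM in mm; 0 is the identity.
#' @return Smoothed [volume3d()].
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("`fwhm_mm` must be a single non-negative number")
  if (fwhm_mm == 0) return(volume)
  sigmas <- fwhm_mm / (2 * sqrt(2 * log(2))) / volume$spacing
  a <- volume$data
  for (axis in 1:3) a <- smooth_axis(a, sigmas[axis], axis)
  volume3d(a, volume$spacing, volume$mask)
}

# 1D Gaussian convolution along one array axis, mirror reflection at edges.
smooth_axis <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-0.5 * (seq(-h, h) / sigma)^2)
  k <- k / sum(k)
  n <- dim(a)[axis]
  out <- array(0, dim(a))
  for (t in seq(-h, h)) {
    idx <- seq_len(n) + t
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    sl <- switch(axis,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    out <- out + k[t + h + 1L] * sl
  }
  out
}

#' Whole-brain SUVR normalization
#'
#' Divides every voxel by the mean intensity over the mask (the whole-brain
#' reference), so the masked mean of the result is exactly 1. Idempotent.
#'
#' @param volume A [volume3d()].
#' @param mask Optional logical array overriding `volume$mask`.
#' @return Normalized [volume3d()].
#' @export
to_suvr <- function(volume, mask = NULL) {
  m <- if (is.null(mask)) volume$mask else mask
  if (!any(m)) stop("empty mask")
  ref <- mean(volume$data[m])
  if (!is.finite(ref) || ref <= 0) stop("mask mean must be positive")
  volume3d(volume$data / ref, volume$spacing, m)
}

#' Per-image z-score normalization
#'
#' Centers and scales by the mean and population standard deviation over
#' mask voxels; voxels outside the mask are set to 0. This is the
#' normalization applied to network inputs. Idempotent.
#'
#' @inheritParams to_suvr
#' @return Standardized [volume3d()].
#' @export
zscore_image <- function(volume, mask = NULL) {
  m <- if (is.null(mask)) volume$mask else mask
  if (!any(m)) stop("empty mask")
  v <- volume$data[m]
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))  # population sd
  if (sdv <= 0) stop("zero variance over mask")
  out <- array(0, dim(volume$data))
  out[m] <- (v - mu) / sdv
  volume3d(out, volume$spacing, m)
}

#' Trilinear resize of a volume
#'
#' Cell-centered trilinear interpolation to a new grid shape (used to bring
#' volumes to the Transformer channel's input geometry). Spacing is rescaled
#' to preserve physical extent; the mask is resampled by majority.
#'
#' @param volume A [volume3d()].
#' @param shape Integer length-3 target shape.
#' @return Resized [volume3d()].
#' @export
resize_volume <- function(volume, shape) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("bad target shape")
  od <- dim(volume$data)
  if (identical(od, shape)) return(volume)
  data <- resize_trilinear(volume$data, shape)
  mask <- resize_trilinear(array(as.numeric(volume$mask), od), shape) > 0.5
  volume3d(data, volume$spacing * od / shape, array(mask, shape))
}

resize_trilinear <- function(arr, shape) {
  od <- dim(arr)
  ax <- lapply(1:3, function(a) {
    p <- (seq_len(shape[a]) - 0.5) * od[a] / shape[a] + 0.5
    p <- pmin(pmax(p, 1), od[a])
    lo <- pmin(floor(p), od[a] - ifelse(od[a] > 1, 1, 0))
    list(lo = as.integer(lo), fr = p - lo)
  })
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  out <- numeric(nx * ny * nz)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx) ax[[1]]$fr else 1 - ax[[1]]$fr
    wy <- if (cy) ax[[2]]$fr else 1 - ax[[2]]$fr
    wz <- if (cz) ax[[3]]$fr else 1 - ax[[3]]$fr
    jx <- pmin(ax[[1]]$lo + cx, od[1])
    jy <- pmin(ax[[2]]$lo + cy, od[2])
    jz <- pmin(ax[[3]]$lo + cz, od[3])
    w <- wx[ix] * wy[iy] * wz[iz]
    out <- out + w * arr[cbind(jx[ix], jy[iy], jz[iz])]
  }
  array(out, shape)
}
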