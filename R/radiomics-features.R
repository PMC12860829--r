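# The 107-feature radiomics bank: 18 first-order, 14 shape, 24 GLCM,
# 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM. Feature definitions follow the
# IBSI-style conventions of the standard radiomics feature banks; degenerate
# ROIs (constant intensity, single voxel) take their analytic limits where
# the limit is finite (documented per family below).

radiomics_families <- function() {
  c("firstorder", "shape", "glcm", "glrlm", "glszm", "ngtdm", "gldm")
}

log2p <- function(p) ifelse(p > 0, log2(p), 0)

features_firstorder <- function(droi) {
  x <- droi$values
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p <- tabulate(droi$levels[droi$levels > 0], droi$ng) / n
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  inr <- x[x >= q[1] & x <= q[5]]
  vv <- prod(droi$spacing)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2p(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(inr - mean(inr))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}

# Shape descriptors use the voxelized surface (exposed voxel faces) and
# voxel-count volume rather than a triangulated mesh; principal-axis lengths
# come from the eigenvalues of the physical voxel-centre covariance.
features_shape <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  vv <- prod(spacing)
  vol <- n * vv
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  area <- 0
  dims <- dim(mask)
  for (a in 1:3) {
    shift <- function(off) {
      i2 <- idx
      i2[, a] <- i2[, a] + off
      inside <- i2[, a] >= 1 & i2[, a] <= dims[a]
      cov <- logical(n)
      cov[inside] <- mask[i2[inside, , drop = FALSE]]
      cov
    }
    area <- area + face_area[a] * (sum(!shift(1L)) + sum(!shift(-1L)))
  }
  pts <- sweep(idx, 2, spacing, `*`)
  border <- border_voxels(mask, idx)
  bpts <- pts[border, , drop = FALSE]
  d3 <- max_pair_dist(bpts)
  d_xy <- max_planar_diam(bpts, 3)
  d_xz <- max_planar_diam(bpts, 2)
  d_yz <- max_planar_diam(bpts, 1)
  ev <- if (n > 1) {
    cv <- stats::cov(pts) * (n - 1) / n
    pmax(sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE), 0)
  } else c(0, 0, 0)
  c(MeshVolume = vol,
    VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / area,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_xy,
    Maximum2DDiameterColumn = d_xz,
    Maximum2DDiameterRow = d_yz,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}

border_voxels <- function(mask, idx) {
  dims <- dim(mask)
  on_border <- rep(FALSE, nrow(idx))
  for (a in 1:3) for (off in c(-1L, 1L)) {
    i2 <- idx
    i2[, a] <- i2[, a] + off
    inside <- i2[, a] >= 1 & i2[, a] <= dims[a]
    nb <- rep(FALSE, nrow(idx))
    nb[inside] <- mask[i2[inside, , drop = FALSE]]
    on_border <- on_border | !nb
  }
  on_border
}

max_pair_dist <- function(p) {
  if (nrow(p) < 2) return(0)
  d2 <- 0
  # row-blocked pairwise distances to bound memory
  bs <- 512L
  for (i0 in seq(1L, nrow(p), by = bs)) {
    blk <- p[i0:min(nrow(p), i0 + bs - 1L), , drop = FALSE]
    cross <- outer(rowSums(blk^2), rowSums(p^2), `+`) - 2 * blk %*% t(p)
    d2 <- max(d2, max(cross))
  }
  sqrt(max(d2, 0))
}

max_planar_diam <- function(p, drop_axis) {
  if (nrow(p) < 2) return(0)
  keep <- setdiff(1:3, drop_axis)
  groups <- split(seq_len(nrow(p)), p[, drop_axis])
  max(vapply(groups, function(g)
    max_pair_dist(p[g, keep, drop = FALSE]), 0))
}

features_glcm <- function(tm) {
  P <- tm$P
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mux <- sum(seq_len(ng) * px)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  # difference and sum distributions
  pd <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), 0)
  ps <- vapply(2:(2 * ng), function(k) sum(P[(i + j) == k]), 0)
  kd <- 0:(ng - 1); ks <- 2:(2 * ng)
  da <- sum(kd * pd)
  hx <- -sum(px * log2p(px))
  hxy <- -sum(P * log2p(P))
  pxy <- outer(px, px)
  hxy1 <- -sum(P * log2p(pxy))
  hxy2 <- -sum(pxy * log2p(pxy))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sigx > 0)
    (sum(i * j * P) - mux^2) / sigx^2 else 1
  mcc <- glcm_mcc(P, px)
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - 2 * mux)^4 * P),
    ClusterShade = sum((i + j - 2 * mux)^3 * P),
    ClusterTendency = sum((i + j - 2 * mux)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * log2p(pd)),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps * log2p(ps)),
    SumSquares = sum((i - mux)^2 * P))
}

glcm_mcc <- function(P, px) {
  keep <- which(px > 0)
  if (length(keep) < 2) return(1)
  Pk <- P[keep, keep, drop = FALSE]
  pk <- px[keep]
  # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) px(k)); marginals are symmetric
  Q <- sweep(Pk, 1, pk, `/`) %*% t(sweep(Pk, 2, pk, `/`))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(ev[2], 0))
}

# Run/zone/dependence banks share the same weighted-sum structure over a
# level x size matrix; `wfun(i, j)` supplies the weight.
rlm_sum <- function(M, wfun) {
  i <- row(M); j <- col(M)
  sum(wfun(i, j) * M)
}

features_glrlm <- function(tm, n_voxels) {
  R <- tm$counts
  nr <- sum(R)
  np <- rlm_sum(R, function(i, j) j)  # voxel coverage across directions
  p <- R / nr
  mui <- rlm_sum(p, function(i, j) i)
  muj <- rlm_sum(p, function(i, j) j)
  c(ShortRunEmphasis = rlm_sum(R, function(i, j) 1 / j^2) / nr,
    LongRunEmphasis = rlm_sum(R, function(i, j) j^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(R)^2) / nr^2,
    RunLengthNonUniformity = sum(colSums(R)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(R)^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = rlm_sum(p, function(i, j) (i - mui)^2),
    RunVariance = rlm_sum(p, function(i, j) (j - muj)^2),
    RunEntropy = -sum(p * log2p(p)),
    LowGrayLevelRunEmphasis = rlm_sum(R, function(i, j) 1 / i^2) / nr,
    HighGrayLevelRunEmphasis = rlm_sum(R, function(i, j) i^2) / nr,
    ShortRunLowGrayLevelEmphasis =
      rlm_sum(R, function(i, j) 1 / (i^2 * j^2)) / nr,
    ShortRunHighGrayLevelEmphasis =
      rlm_sum(R, function(i, j) i^2 / j^2) / nr,
    LongRunLowGrayLevelEmphasis =
      rlm_sum(R, function(i, j) j^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis =
      rlm_sum(R, function(i, j) i^2 * j^2) / nr)
}

features_glszm <- function(tm, n_voxels) {
  Z <- tm$counts
  nz <- sum(Z)
  p <- Z / nz
  mui <- rlm_sum(p, function(i, j) i)
  muj <- rlm_sum(p, function(i, j) j)
  c(SmallAreaEmphasis = rlm_sum(Z, function(i, j) 1 / j^2) / nz,
    LargeAreaEmphasis = rlm_sum(Z, function(i, j) j^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(Z)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(Z)^2) / nz^2,
    SizeZoneNonUniformity = sum(colSums(Z)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(colSums(Z)^2) / nz^2,
    ZonePercentage = nz / n_voxels,
    GrayLevelVariance = rlm_sum(p, function(i, j) (i - mui)^2),
    ZoneVariance = rlm_sum(p, function(i, j) (j - muj)^2),
    ZoneEntropy = -sum(p * log2p(p)),
    LowGrayLevelZoneEmphasis = rlm_sum(Z, function(i, j) 1 / i^2) / nz,
    HighGrayLevelZoneEmphasis = rlm_sum(Z, function(i, j) i^2) / nz,
    SmallAreaLowGrayLevelEmphasis =
      rlm_sum(Z, function(i, j) 1 / (i^2 * j^2)) / nz,
    SmallAreaHighGrayLevelEmphasis =
      rlm_sum(Z, function(i, j) i^2 / j^2) / nz,
    LargeAreaLowGrayLevelEmphasis =
      rlm_sum(Z, function(i, j) j^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis =
      rlm_sum(Z, function(i, j) i^2 * j^2) / nz)
}

features_ngtdm <- function(tm) {
  m <- tm$counts
  ni <- m[, 1]; s <- m[, 2]
  nvp <- sum(ni)
  if (nvp == 0) {
    # no voxel has an in-ROI neighbour (single-voxel ROI)
    return(c(Coarseness = 1e6, Contrast = 0, Busyness = 0, Complexity = 0,
             Strength = 0))
  }
  p <- ni / nvp
  lev <- seq_len(nrow(m))
  act <- which(p > 0)
  ngp <- length(act)
  coars_den <- sum(p * s)
  contrast <- if (ngp > 1) {
    (sum(outer(p[act], p[act]) * outer(lev[act], lev[act], `-`)^2) /
       (ngp * (ngp - 1))) * (sum(s) / nvp)
  } else 0
  busy_den <- sum(abs(outer(lev[act] * p[act], lev[act] * p[act], `-`)))
  complexity <- if (ngp > 0) {
    pi_ <- p[act]; si <- s[act]; li <- lev[act]
    sum(abs(outer(li, li, `-`)) *
          (outer(pi_ * si, pi_ * si, `+`)) / outer(pi_, pi_, `+`)) / nvp
  } else 0
  strength <- if (sum(s) > 0 && ngp > 1) {
    sum(outer(p[act], p[act], `+`) * outer(lev[act], lev[act], `-`)^2) /
      sum(s)
  } else 0
  c(Coarseness = if (coars_den > 0) 1 / coars_den else 1e6,
    Contrast = contrast,
    Busyness = if (busy_den > 0) coars_den / busy_den else 0,
    Complexity = complexity,
    Strength = strength)
}

features_gldm <- function(tm) {
  D <- tm$counts
  nd <- sum(D)
  p <- D / nd
  mui <- rlm_sum(p, function(i, j) i)
  muj <- rlm_sum(p, function(i, j) j)
  c(SmallDependenceEmphasis = rlm_sum(D, function(i, j) 1 / j^2) / nd,
    LargeDependenceEmphasis = rlm_sum(D, function(i, j) j^2) / nd,
    GrayLevelNonUniformity = sum(rowSums(D)^2) / nd,
    DependenceNonUniformity = sum(colSums(D)^2) / nd,
    DependenceNonUniformityNormalized = sum(colSums(D)^2) / nd^2,
    GrayLevelVariance = rlm_sum(p, function(i, j) (i - mui)^2),
    DependenceVariance = rlm_sum(p, function(i, j) (j - muj)^2),
    DependenceEntropy = -sum(p * log2p(p)),
    LowGrayLevelEmphasis = rlm_sum(D, function(i, j) 1 / i^2) / nd,
    HighGrayLevelEmphasis = rlm_sum(D, function(i, j) i^2) / nd,
    SmallDependenceLowGrayLevelEmphasis =
      rlm_sum(D, function(i, j) 1 / (i^2 * j^2)) / nd,
    SmallDependenceHighGrayLevelEmphasis =
      rlm_sum(D, function(i, j) i^2 / j^2) / nd,
    LargeDependenceLowGrayLevelEmphasis =
      rlm_sum(D, function(i, j) j^2 / i^2) / nd,
    LargeDependenceHighGrayLevelEmphasis =
      rlm_sum(D, function(i, j) i^2 * j^2) / nd)
}

#' Compute the radiomics feature bank for one ROI
#'
#' Returns the full default bank for the enabled families — 107 named values
#' when all seven are on (18 first-order, 14 shape, 24 GLCM, 16 GLRLM,
#' 16 GLSZM, 5 NGTDM, 14 GLDM). Names are `<family>_<Feature>`.
#'
#' @param volume A [volume3d()] (intensities on the scale `bin_width` refers
#'   to; the pipeline uses SUVR volumes).
#' @param roi_mask Logical array selecting the ROI.
#' @param families Subset of [radiomics_families()].
#' @param bin_width Discretization bin width (default 0.05, SUVR scale).
#' @return Named numeric vector of feature values.
#' @export
compute_features <- function(volume, roi_mask,
                             families = radiomics_families(),
                             bin_width = 0.05) {
  families <- match.arg(families, radiomics_families(), several.ok = TRUE)
  if (!any(roi_mask)) stop("empty ROI")
  droi <- discretize(volume, roi_mask, bin_width)
  out <- c()
  for (fam in families) {
    vals <- switch(fam,
      firstorder = features_firstorder(droi),
      shape = features_shape(droi$mask, volume$spacing),
      glcm = features_glcm(texture_matrix(droi, "glcm")),
      glrlm = features_glrlm(texture_matrix(droi, "glrlm"), droi$n_voxels),
      glszm = features_glszm(texture_matrix(droi, "glszm"), droi$n_voxels),
      ngtdm = features_ngtdm(texture_matrix(droi, "ngtdm")),
      gldm = features_gldm(texture_matrix(droi, "gldm")))
    names(vals) <- paste0(fam, "_", names(vals))
    out <- c(out, vals)
  }
  out
}
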