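test_that("discretization follows the min-anchored fixed-bin-width rule", {
  d <- c(11, 1, 1)
  v <- volume3d(array(0:10, d), c(1, 1, 1), array(TRUE, d))
  dr <- discretize(v, array(TRUE, d), bin_width = 5)
  expect_equal(as.integer(dr$levels), c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 3))
  expect_equal(dr$ng, 3L)
  # translation invariance
  v2 <- volume3d(array(0:10 + 17.3, d), c(1, 1, 1), array(TRUE, d))
  dr2 <- discretize(v2, array(TRUE, d), 5)
  expect_identical(dr2$levels, dr$levels)
  # constant ROI
  vc <- volume3d(array(4, c(3, 3, 3)), c(1, 1, 1), array(TRUE, c(3, 3, 3)))
  drc <- discretize(vc, array(TRUE, c(3, 3, 3)), 0.5)
  expect_equal(drc$ng, 1L)
  expect_true(all(drc$levels == 1))
  expect_error(discretize(v, array(FALSE, d), 1), "empty ROI")
  expect_error(discretize(v, array(TRUE, d), 0), "bin_width")
})

test_that("the full bank yields 107 named features with the documented split", {
  v <- tiny_volume(1, d = c(7, 7, 7))
  f <- compute_features(v, array(TRUE, c(7, 7, 7)), bin_width = 0.25)
  expect_length(f, 107)
  expect_false(any(duplicated(names(f))))
  fam <- sub("_.*", "", names(f))
  expect_equal(as.integer(table(fam)[c("firstorder", "shape", "glcm",
                                       "glrlm", "glszm", "ngtdm", "gldm")]),
               c(18L, 14L, 24L, 16L, 16L, 5L, 14L))
})

test_that("constant ROIs take their analytically forced values", {
  d <- c(4, 4, 4)
  v <- volume3d(array(2, d), c(1, 2, 3), array(TRUE, d))
  f <- compute_features(v, array(TRUE, d), bin_width = 0.1)
  expect_equal(f[["firstorder_Range"]], 0)
  expect_equal(f[["firstorder_Variance"]], 0)
  expect_equal(f[["firstorder_Entropy"]], 0)
  expect_equal(f[["firstorder_Uniformity"]], 1)
  expect_equal(f[["firstorder_Energy"]], 64 * 4)
  expect_equal(f[["glcm_Contrast"]], 0)
  expect_equal(f[["glcm_ClusterProminence"]], 0)
  expect_equal(f[["glcm_DifferenceAverage"]], 0)
  expect_equal(f[["glcm_JointEnergy"]], 1)
  expect_equal(f[["shape_VoxelVolume"]], 64 * 6)
})

test_that("GLCM on a constant 3x3x3 ROI is the 1x1 certain distribution", {
  dr <- droi_from_levels(array(1L, c(3, 3, 3)))
  tm <- texture_matrix(dr, "glcm")
  expect_equal(dim(tm$P), c(1L, 1L))
  expect_equal(sum(tm$P), 1)
})

test_that("single-voxel ROIs give one unit run and defined first-order values", {
  lev <- array(0L, c(3, 3, 3))
  lev[2, 2, 2] <- 1L
  tm <- texture_matrix(droi_from_levels(lev), "glrlm")
  expect_equal(sum(tm$counts), 13)  # one length-1 run per direction
  expect_true(all(tm$counts[1, 1] == 13))
  v <- volume3d(array(5, c(3, 3, 3)), c(2, 2, 2), array(TRUE, c(3, 3, 3)))
  roi <- array(FALSE, c(3, 3, 3)); roi[2, 2, 2] <- TRUE
  f <- compute_features(v, roi, bin_width = 0.1)
  expect_equal(f[["firstorder_Mean"]], 5)
  expect_equal(f[["shape_VoxelVolume"]], 8)
  expect_true(all(is.finite(f[c("shape_Elongation", "shape_Flatness")])))
})

test_that("SRHGLE on the 4x1x1 toy matches direction-summed enumeration", {
  lev <- array(c(1L, 1L, 2L, 3L), c(4, 1, 1))
  dr <- droi_from_levels(lev)
  f <- petfusion:::features_glrlm(texture_matrix(dr, "glrlm"), dr$n_voxels)
  # along x: runs {(1,len2),(2,len1),(3,len1)}; the 12 off-axis directions
  # each contribute 4 unit runs (levels 1,1,2,3)
  num <- (1 / 4 + 4 + 9) + 12 * (1 + 1 + 4 + 9)
  nr <- 3 + 12 * 4
  expect_equal(f[["ShortRunHighGrayLevelEmphasis"]], num / nr)
  # cross-check against the brute-force oracle matrix
  R <- oracle_glrlm(lev, 3)
  i <- row(R); j <- col(R)
  expect_equal(f[["ShortRunHighGrayLevelEmphasis"]],
               sum(R * i^2 / j^2) / sum(R))
})

test_that("feature values ignore bounding-box padding and subject order", {
  set.seed(6)
  small <- array(abs(rnorm(5 * 5 * 5)) + 1, c(5, 5, 5))
  big <- array(0, c(11, 11, 11))
  big[4:8, 4:8, 4:8] <- small
  roi_small <- array(TRUE, c(5, 5, 5))
  roi_big <- array(FALSE, c(11, 11, 11))
  roi_big[4:8, 4:8, 4:8] <- TRUE
  f1 <- compute_features(volume3d(small, c(2, 2, 2), roi_small), roi_small,
                         bin_width = 0.2)
  f2 <- compute_features(volume3d(big, c(2, 2, 2),
                                  array(TRUE, c(11, 11, 11))), roi_big,
                         bin_width = 0.2)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("extract_table produces region x family x feature columns", {
  co <- desk_cohort(2, seed = 3)
  tab <- extract_table(co, co$atlas)
  expect_equal(ncol(tab$values), 20 * 107)
  expect_equal(nrow(tab$values), 6)
  expect_false(any(duplicated(colnames(tab$values))))
  expect_true(all(grepl("^(frontal|parietal|occipital|temporal|sub|nucleus|ventral|locus|raphe|dentate|substantia|red|thalamic|caudate|putamen|globus|thalamus|medulla|midbrain|pons)",
                        colnames(tab$values))))
  # a single-region atlas gives exactly one 107-feature block
  atl1 <- one_region_atlas(dim(co$atlas$labels), co$atlas$spacing)
  tab1 <- extract_table(co, atl1)
  expect_equal(ncol(tab1$values), 107)
  expect_true(all(startsWith(colnames(tab1$values), "putamen_")))
})

test_that("row order follows the cohort and permuting subjects permutes rows", {
  co <- desk_cohort(2, seed = 3)
  tab <- extract_table(co, co$atlas)
  co_rev <- co
  co_rev$subjects <- rev(co$subjects)
  tab_rev <- extract_table(co_rev, co$atlas)
  expect_identical(tab_rev$values, tab$values[rev(seq_len(6)), ])
})

test_that("feature normalization matches reference statistics", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 2] * 2 + 10
  tab <- feature_table(X, rep("IPD", 20))
  self <- normalize_table(tab)
  expect_equal(unname(colMeans(self$values)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(self$values, 2, sd)), c(1, 1, 1),
               tolerance = 1e-12)
  # a value of 14 in a column with reference mu 10, sd 2 maps to 2.0
  ref <- feature_table(cbind(z = rnorm(50, 10, 2)), rep("IPD", 50))
  ref$values[, 1] <- (ref$values[, 1] - mean(ref$values[, 1])) /
    sd(ref$values[, 1]) * 2 + 10
  tst <- feature_table(cbind(z = c(14, 10)), rep("IPD", 2))
  out <- normalize_table(tst, ref)
  expect_equal(unname(out$values[, 1]), c(2, 0), tolerance = 1e-12)
  # zero-variance reference columns are flagged and dropped
  refc <- feature_table(cbind(a = rnorm(10), flat = rep(1, 10)),
                        rep("IPD", 10))
  outc <- normalize_table(refc)
  expect_equal(colnames(outc$values), "a")
  expect_equal(outc$meta$dropped, "flat")
})
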