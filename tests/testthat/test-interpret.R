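linear_model <- function(w) function(m) cbind(m %*% w)

test_that("exact Shapley obeys dummy, efficiency, and symmetry", {
  set.seed(1)
  bg <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- c(a = 1.2, b = -0.4, c = 2.0)
  # dummy: a model ignoring everything attributes nothing
  sh0 <- shapley_exact(function(m) cbind(rep(4, nrow(m))), bg, x)
  expect_true(all(sh0$phi == 0))
  expect_equal(sh0$base[1], 4)
  # efficiency on a nonlinear model
  f <- function(m) cbind(m[, 1] * m[, 2] + exp(m[, 3] / 3))
  sh <- shapley_exact(f, bg, x)
  expect_lt(abs(sum(sh$phi[, 1]) + sh$base[1] - f(matrix(x, 1))[1]), 1e-8)
  # symmetry: interchangeable features get equal attribution
  bgs <- cbind(p = bg[, 1], q = bg[, 1])
  xs <- c(p = 1.5, q = 1.5)
  shs <- shapley_exact(function(m) cbind(m[, 1] + m[, 2]), bgs, xs)
  expect_equal(unname(shs$phi[1, 1]), unname(shs$phi[2, 1]),
               tolerance = 1e-10)
})

test_that("exact Shapley matches the linear-model closed form", {
  set.seed(2)
  bg <- matrix(rnorm(100), 25, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  w <- c(2, -1, 0.5, 3)
  x <- setNames(rnorm(4), paste0("f", 1:4))
  sh <- shapley_exact(linear_model(w), bg, x)
  expect_equal(unname(sh$phi[, 1]), unname(w * (x - colMeans(bg))),
               tolerance = 1e-10)
  expect_error(shapley_exact(linear_model(w), bg[0, ], x), "nonempty")
})

test_that("multi-output models get per-class attributions", {
  set.seed(3)
  bg <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  W <- cbind(c(1, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, -1, 1))
  f <- function(m) m %*% W
  x <- setNames(rnorm(4), paste0("f", 1:4))
  sh <- shapley_exact(f, bg, x)
  expect_equal(dim(sh$phi), c(4L, 3L))
  for (k in 1:3)
    expect_equal(unname(sh$phi[, k]),
                 unname(W[, k] * (x - colMeans(bg))), tolerance = 1e-10)
})

test_that("the permutation estimator converges to the exact values", {
  set.seed(4)
  F <- 8
  bg <- matrix(rnorm(20 * F), 20, F,
               dimnames = list(NULL, paste0("f", 1:F)))
  f <- function(m) cbind(m[, 1] * m[, 2] + m[, 3]^2 - 2 * m[, 4] +
                           0.5 * m[, 5] * m[, 8])
  x <- setNames(rnorm(F), paste0("f", 1:F))
  ex <- shapley_exact(f, bg, x)
  sa <- shapley_sampled(f, bg, x, n_permutations = 2000, seed = 5)
  expect_true(all(abs(sa$phi - ex$phi) <= 3 * pmax(sa$se, 1e-6)))
  # additivity is enforced exactly
  expect_lt(abs(sum(sa$phi[, 1]) + sa$base[1] - sa$fx[1]), 1e-8)
  # more permutations shrink the Monte-Carlo error
  s500 <- shapley_sampled(f, bg, x, 500, seed = 6)
  s2000 <- shapley_sampled(f, bg, x, 2000, seed = 6)
  expect_lt(median(s2000$se), median(s500$se))
})

test_that("importance profiles are mean absolute attributions", {
  phi <- array(0, c(2, 3, 1))
  phi[, 1, 1] <- c(1, -3)
  sm <- structure(list(phi = phi, base = 0, features = c("a", "b", "c"),
                       classes = "X"), class = "pf_shap")
  ip <- importance_profile(sm)
  expect_equal(unname(ip$importance["a", "X"]), 2)
  expect_equal(unname(ip$importance["b", "X"]), 0)
  expect_equal(ip$ranking$X[1], "a")
  # all-zero attributions give an all-zero profile
  sm0 <- sm; sm0$phi[] <- 0
  expect_true(all(importance_profile(sm0)$importance == 0))
})

test_that("concordance follows the Pearson closed forms", {
  mk <- function(v) structure(list(importance = matrix(v, ncol = 1,
                                                       dimnames = list(
                                                         c("a", "b", "c"),
                                                         "MSA"))),
                              class = "pf_importance")
  expect_equal(cohort_concordance(mk(c(1, 2, 3)), mk(c(1, 2, 3)))$r, 1)
  expect_equal(cohort_concordance(mk(c(1, 2, 3)), mk(c(2, 4, 6)))$r, 1)
  expect_equal(cohort_concordance(mk(c(1, 2, 3)), mk(c(3, 1, 2)))$r, -0.5,
               tolerance = 1e-12)
  small <- structure(list(importance = matrix(c(1, 2), ncol = 1,
                                              dimnames = list(c("a", "b"),
                                                              "MSA"))),
                     class = "pf_importance")
  expect_error(cohort_concordance(small, small), "shared")
})

test_that("group averaging preserves identical maps and flattens complements", {
  set.seed(7)
  m1 <- attribution_volume(array(runif(27), c(3, 3, 3)), c(1, 1, 1),
                           "MSA", "layer_cam")
  g1 <- group_average_map(list(m1, m1, m1))
  expect_equal(g1$data, m1$data, tolerance = 1e-12)
  comp <- attribution_volume(1 - m1$data, c(1, 1, 1), "MSA", "layer_cam")
  g2 <- group_average_map(list(m1, comp))
  # the voxelwise mean is constant 0.5, which min-max normalizes to zero
  expect_true(all(g2$data == 0))
  expect_error(group_average_map(list()), "empty")
  bad <- attribution_volume(array(0.3, c(2, 2, 2)), c(1, 1, 1), "x", "y")
  expect_error(group_average_map(list(m1, bad)), "mismatch")
})

test_that("region contrast summarizes maps against the atlas", {
  atl <- one_region_atlas(c(10, 10, 10))
  m <- array(0.1, c(10, 10, 10))
  m[atl$labels == 1] <- 0.9
  # add a second labelled region to serve as the unaffected reference
  atl$labels[1:2, 1:2, 1:2] <- 2L
  atl$registry <- c(`1` = "putamen", `2` = "pons")
  map <- attribution_volume(m, c(2, 2, 2), "MSA", "layer_cam")
  ct <- attribution_region_contrast(map, atl, "putamen")
  expect_gt(ct$ratio, 1)
  expect_error(attribution_region_contrast(map, atl, "nonexistent_region"),
               "unknown region")
})
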