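make_table <- function(X, labels, id = "c") {
  feature_table(as.matrix(X), labels, id)
}

test_that("stability filter drops constant and distribution-shifted columns", {
  set.seed(1)
  n <- 200
  A <- cbind(flat = rep(1, n), stable = rnorm(n), shifted = rnorm(n))
  B <- cbind(flat = rep(1, n), stable = rnorm(n), shifted = rnorm(n, 3))
  lab <- rep(c("IPD", "MSA"), n / 2)
  st <- stability_filter(make_table(A, lab), make_table(B, lab))
  expect_setequal(st$retained, "stable")
  expect_equal(sort(st$audit$column), c("flat", "shifted"))
  expect_equal(st$audit$reason[st$audit$column == "flat"], "low_variance")
  expect_equal(st$audit$reason[st$audit$column == "shifted"],
               "ks_distribution")
  # independent check: the KS statistic for N(0,1) vs N(3,1) far exceeds
  # the asymptotic 1% critical value
  Dn <- max(abs(ecdf(A[, 3])(sort(c(A[, 3], B[, 3]))) -
                  ecdf(B[, 3])(sort(c(A[, 3], B[, 3])))))
  crit <- 1.63 * sqrt(2 / n)  # c(0.01) sqrt((n+m)/(nm))
  expect_gt(Dn, crit)
  # identical cohorts lose nothing to the distribution rule
  st2 <- stability_filter(make_table(A[, 2:3], lab), make_table(A[, 2:3],
                                                                lab))
  expect_setequal(st2$retained, c("stable", "shifted"))
})

test_that("the elastic net hits its boundary cases", {
  set.seed(2)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- drop(X %*% c(2, -1, 0.5, 0)) + rnorm(n, 0, 0.2)
  # enormous lambda zeroes everything
  big <- petfusion:::cpp_enet_path(X, y, 0.5, c(1e6), 1e-10, 1000)
  expect_true(all(big$beta == 0))
  # lambda -> 0 recovers least squares on a full-rank design
  ols <- coef(lm(y ~ X))
  zero <- petfusion:::cpp_enet_path(X, y, 0.7, c(0), 1e-12, 20000)
  expect_equal(unname(zero$beta[, 1]), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(zero$intercept[1], unname(ols[1]), tolerance = 1e-6)
})

test_that("coordinate descent matches the orthonormal soft-threshold form", {
  set.seed(3)
  n <- 80; p <- 10
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1] * sqrt(n)
  X <- Q
  colnames(X) <- paste0("f", 1:p)
  y <- drop(X %*% c(3, -2, 1.5, rep(0, 5), 0.8, 0)) + rnorm(n, 0, 0.3)
  bols <- drop(crossprod(X, y - mean(y))) / n
  for (alpha in c(0.25, 0.5, 1)) {
    for (lam in c(0.05, 0.3, 0.9, 2)) {
      fit <- petfusion:::cpp_enet_path(X, y, alpha, c(lam), 1e-12, 20000)
      soft <- sign(bols) * pmax(abs(bols) - lam * alpha, 0) /
        (1 + lam * (1 - alpha))
      expect_lt(max(abs(fit$beta[, 1] - soft)), 1e-8)
    }
  }
})

test_that("the path agrees with glmnet on a shared objective", {
  set.seed(4)
  X <- matrix(rnorm(150 * 30), 150, 30)
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(150)
  y <- y / sd(y)  # glmnet interprets lambda on the unit-variance-y scale
  for (alpha in c(0.5, 1)) {
    g <- glmnet::glmnet(X, y, alpha = alpha, lambda = c(0.3, 0.1),
                        standardize = FALSE, thresh = 1e-14)
    f <- petfusion:::cpp_enet_path(X, y, alpha, c(0.3, 0.1), 1e-10, 20000)
    expect_lt(max(abs(as.matrix(g$beta) - f$beta)), 1e-3)
  }
})

test_that("CV selects a sparse informative model on planted signal", {
  set.seed(5)
  n <- 120; p <- 40
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- as.numeric(rep(c(0, 1), each = n / 2))
  X[y == 1, 1:3] <- X[y == 1, 1:3] + 1.2
  fit <- elastic_net_path(X, y, alpha = 0.5, folds = 10, seed = 2)
  expect_true(all(c("f01", "f02", "f03") %in% fit$retained))
  expect_lt(length(fit$retained), p / 2)
  expect_equal(fit$lambda[which.min(fit$cvm)], fit$lambda_min)
})

test_that("cross-cohort refinement keeps shared-support correlated features", {
  W <- matrix(c(1, 2, 3, 0.5, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  ra <- list(weights = W, support = c("a", "b"))
  rb <- list(weights = W * 2, support = c("a", "b"))
  expect_setequal(cross_cohort_refine(ra, rb, 0.6), c("a", "b"))
  # a feature absent from cohort B support is dropped
  rb2 <- list(weights = W * 2, support = "a")
  expect_equal(cross_cohort_refine(ra, rb2, 0.6), "a")
  # anti-correlated weight profiles fail the threshold
  W2 <- W; W2["a", ] <- c(3, 2, 1)
  rb3 <- list(weights = W2, support = c("a", "b"))
  expect_false("a" %in% cross_cohort_refine(ra, rb3, 0.6))
  expect_error(cross_cohort_refine(ra, list(weights = W, support = "zz")),
               "empty")
})

test_that("greedy redundancy pruning follows the documented trace", {
  set.seed(6)
  n <- 400
  base <- rnorm(n)
  v1 <- base + rnorm(n, 0, 0.3)           # r(1,2) ~ 0.9
  v2 <- base + rnorm(n, 0, 0.3)
  v3 <- rnorm(n)                          # near-uncorrelated
  vals <- cbind(f1 = v1, f2 = v2, f3 = v3)
  kept <- prune_redundant(vals, c(f1 = 3, f2 = 2, f3 = 1), 0.5)
  expect_equal(kept, c("f1", "f3"))
  # identical columns: the heavier-weighted one survives
  dup <- cbind(x = base, y = base)
  expect_equal(prune_redundant(dup, c(x = 1, y = 2), 0.5), "y")
  # mutually uncorrelated columns all survive
  ind <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("u", "v", "w")))
  expect_length(prune_redundant(ind, c(u = 1, v = 2, w = 3), 0.5), 3)
  expect_length(prune_redundant(ind[, 0], numeric(0), 0.5), 0)
})

test_that("the cascade is monotone with a complete audit", {
  sim <- simulate_feature_tables(n_per_class = 30, p = 40,
                                 n_informative = 4, effect = 1.0, seed = 8)
  tabs <- lapply(sim$tables, normalize_table)
  lat <- function(s) {
    set.seed(s)
    list(local = matrix(rnorm(90 * 6), 90, 6,
                        dimnames = list(NULL, paste0("Local_latent_", 0:5))),
         global = matrix(rnorm(90 * 6), 90, 6,
                         dimnames = list(NULL, paste0("Global_latent_",
                                                      0:5))))
  }
  sel <- suppressWarnings(
    select_features(tabs, list(lat(1), lat(2)), sim$labels, seed = 4))
  expect_s3_class(sel, "pf_selection")
  removals <- sum(vapply(sel$audit, nrow, 0L))
  expect_equal(sel$n_input, length(sel$radiomics) + removals)
  expect_true(all(sel$radiomics %in% colnames(tabs[[1]]$values)))
  expect_equal(length(sel$local), 5)
  expect_equal(length(sel$global), 5)
  expect_equal(sel$fused, c(sel$radiomics, sel$local, sel$global))
})

test_that("single-cohort mode skips the cross-cohort rules and says so", {
  sim <- simulate_feature_tables(n_per_class = 30, p = 30,
                                 n_informative = 3, seed = 9, n_cohorts = 1)
  tabs <- list(normalize_table(sim$tables[[1]]))
  lat <- list(list(local = matrix(rnorm(90 * 6), 90, 6,
                                  dimnames = list(NULL,
                                                  paste0("Local_latent_",
                                                         0:5))),
                   global = matrix(rnorm(90 * 6), 90, 6,
                                   dimnames = list(NULL,
                                                   paste0("Global_latent_",
                                                          0:5)))))
  expect_message(
    sel <- suppressWarnings(select_features(tabs, lat, sim$labels,
                                            seed = 2)),
    "single-cohort")
  expect_true(sel$skipped_cross_cohort)
  expect_true(all(sim$informative %in% sel$radiomics))
})

test_that("planted informative features are recovered across seeds", {
  hits <- 0L
  all_in <- 0L
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    sim <- simulate_feature_tables(n_per_class = 40, p = 50,
                                   n_informative = 5, effect = 1.0,
                                   seed = 400 + s)
    tabs <- lapply(sim$tables, normalize_table)
    lat <- function(k) {
      set.seed(1000 * s + k)
      list(local = matrix(rnorm(120 * 6), 120, 6,
                          dimnames = list(NULL, paste0("Local_latent_",
                                                       0:5))),
           global = matrix(rnorm(120 * 6), 120, 6,
                           dimnames = list(NULL, paste0("Global_latent_",
                                                        0:5))))
    }
    sel <- suppressWarnings(select_features(tabs, list(lat(1), lat(2)),
                                            sim$labels, seed = s))
    n_rec <- sum(sim$informative %in% sel$radiomics)
    hits <- hits + (n_rec >= 4)
    all_in <- all_in + (n_rec == 5)
  }
  expect_gte(hits / n_seeds, 0.9)   # >= 4 of 5 recovered almost always
  expect_gte(all_in / n_seeds, 0.8) # all 5 in the fused set most seeds
})

test_that("with zero planted signal the cascade retains almost nothing", {
  retained <- vapply(1:12, function(s) {
    sim <- simulate_feature_tables(n_per_class = 30, p = 40,
                                   n_informative = 0, seed = 600 + s)
    tabs <- lapply(sim$tables, normalize_table)
    lat <- function(k) {
      set.seed(2000 * s + k)
      list(local = matrix(rnorm(90 * 4), 90, 4,
                          dimnames = list(NULL, paste0("Local_latent_",
                                                       0:3))),
           global = matrix(rnorm(90 * 4), 90, 4,
                           dimnames = list(NULL, paste0("Global_latent_",
                                                        0:3))))
    }
    sel <- try(suppressWarnings(
      select_features(tabs, list(lat(1), lat(2)), sim$labels, seed = s)),
      silent = TRUE)
    if (inherits(sel, "try-error")) 0L else length(sel$radiomics)
  }, 0L)
  expect_lte(median(retained), 2)
})
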