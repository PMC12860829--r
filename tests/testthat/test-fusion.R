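toy_blocks <- function(n = 30, seed = 1) {
  set.seed(seed)
  rad <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("putamen_firstorder_f", 1:8)))
  loc <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("Local_latent_", 0:5)))
  glo <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("Global_latent_", 0:5)))
  sel <- list(radiomics = colnames(rad),
              local = paste0("Local_latent_", 0:4),
              global = paste0("Global_latent_", 0:4))
  list(rad = rad, loc = loc, glo = glo, sel = sel)
}

test_that("fusing 8 radiomics with 5+5 latents gives an 18-wide matrix", {
  b <- toy_blocks()
  fused <- fuse_features(b$sel, b$rad, b$loc, b$glo)
  expect_equal(ncol(fused$matrix), 18)
  expect_equal(fused$spec,
               c(b$sel$radiomics, b$sel$local, b$sel$global))
  # latent blocks are z-scored against their own (training) stats
  expect_equal(unname(colMeans(fused$matrix[, 9:18])), rep(0, 10),
               tolerance = 1e-12)
  # radiomics-only ablation keeps width 8
  sel0 <- list(radiomics = b$sel$radiomics, local = character(0),
               global = character(0))
  expect_equal(ncol(fuse_features(sel0, b$rad, b$loc, b$glo)$matrix), 8)
  expect_error(fuse_features(list(radiomics = "nope", local = character(0),
                                  global = character(0)),
                             b$rad, b$loc, b$glo), "missing")
})

test_that("test cohorts reuse training normalization statistics", {
  b <- toy_blocks(seed = 2)
  tr <- fuse_features(b$sel, b$rad, b$loc, b$glo)
  b2 <- toy_blocks(n = 10, seed = 3)
  te <- fuse_features(b$sel, b2$rad, b2$loc, b2$glo,
                      norm_stats = tr$norm_stats)
  # manual z-score of the first test latent column with training stats
  mu <- tr$norm_stats$local$mu[1]
  sd1 <- tr$norm_stats$local$sd[1]
  expect_equal(unname(te$matrix[, 9]),
               unname((b2$loc[, 1] - mu) / sd1), tolerance = 1e-12)
})

test_that("the boosted classifier separates an easy 3-class toy", {
  set.seed(4)
  n <- 30
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  lab <- rep(c("IPD", "MSA", "PSP"), each = n / 3)
  X[lab == "MSA", 1] <- X[lab == "MSA", 1] + 4
  X[lab == "PSP", 2] <- X[lab == "PSP", 2] + 4
  m <- train_classifier(X, lab, classifier_spec(seed = 2))
  expect_equal(mean(predict_class(m, X) == lab), 1.0)
  p <- predict_proba(m, X)
  expect_equal(unname(rowSums(p)), rep(1, n), tolerance = 1e-6)
  expect_true(all(p[cbind(seq_len(n), match(lab, m$classes))] > 0.9))
  # permuting rows permutes predictions identically
  perm <- sample(n)
  expect_equal(predict_proba(m, X[perm, ]), p[perm, ], tolerance = 1e-12)
})

test_that("a constant feature yields majority-class predictions", {
  X <- matrix(1, 40, 1, dimnames = list(NULL, "flat"))
  lab <- c(rep("IPD", 25), rep("MSA", 10), rep("PSP", 5))
  m <- train_classifier(X, lab,
                        classifier_spec(seed = 1, nrounds = 20,
                                        early_stopping_rounds = 0))
  expect_true(all(predict_class(m, X) == "IPD"))
})

test_that("training is deterministic and rejects degenerate input", {
  set.seed(5)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  lab <- rep(c("IPD", "MSA", "PSP"), each = 10)
  m1 <- train_classifier(X, lab, classifier_spec(seed = 7))
  m2 <- train_classifier(X, lab, classifier_spec(seed = 7))
  expect_identical(predict_proba(m1, X), predict_proba(m2, X))
  expect_error(train_classifier(X, rep("IPD", 30)), "2 classes")
  Xn <- X; Xn[1, 1] <- NA
  expect_error(train_classifier(Xn, lab), "NaN")
})

test_that("metrics match hand arithmetic on a fixed confusion matrix", {
  # confusion [[8,1,1],[0,9,1],[1,0,9]] built from synthetic scores
  classes <- c("A", "B", "C")
  truth <- rep(classes, each = 10)
  pred <- c(rep("A", 8), "B", "C",
            rep("B", 9), "C",
            "A", rep("C", 9))
  p <- matrix(0.05, 30, 3, dimnames = list(NULL, classes))
  p[cbind(1:30, match(pred, classes))] <- 0.9
  met <- petfusion:::metrics_from_scores(p, truth, classes)
  expect_equal(met$accuracy, 26 / 30, tolerance = 1e-12)
  expect_equal(unname(met$per_class["A", "recall"]), 0.8)
  expect_equal(unname(met$per_class["A", "precision"]), 8 / 9)
  expect_equal(unname(met$confusion["A", ]), c(8, 1, 1))
  expect_equal(sum(met$confusion), 30)
  # perfect predictions give perfect metrics
  pp <- matrix(0.01, 30, 3, dimnames = list(NULL, classes))
  pp[cbind(1:30, match(truth, classes))] <- 0.98
  mperf <- petfusion:::metrics_from_scores(pp, truth, classes)
  expect_equal(mperf$accuracy, 1)
  expect_equal(mperf$macro_auc, 1)
  expect_equal(mperf$macro_f1, 1)
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(6)
  n <- 2000
  classes <- c("A", "B", "C")
  truth <- sample(classes, n, replace = TRUE)
  p <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, classes))
  p <- p / rowSums(p)
  met <- petfusion:::metrics_from_scores(p, truth, classes)
  expect_lt(abs(met$macro_auc - 0.5), 0.03)
})

test_that("ablations run on consistent feature blocks", {
  set.seed(7)
  b <- toy_blocks(n = 60, seed = 8)
  lab <- rep(c("IPD", "MSA", "PSP"), each = 20)
  b$rad[lab == "MSA", 1] <- b$rad[lab == "MSA", 1] + 3
  b$loc[lab == "PSP", 1] <- b$loc[lab == "PSP", 1] + 3
  tr <- fuse_features(b$sel, b$rad, b$loc, b$glo)
  res <- run_ablations(tr, tr, b$sel, lab, lab,
                       classifier_spec(seed = 3, nrounds = 60))
  expect_named(res, c("radiomics", "radiomics_local", "radiomics_global",
                      "fused"))
  for (m in res) expect_s3_class(m, "pf_metrics")
  # the local latent carries the PSP signal the radiomics block lacks
  expect_gte(res$radiomics_local$macro_auc, res$radiomics$macro_auc - 0.02)
})
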