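test_that("patch token counts follow the sliding-window formula", {
  v <- volume3d(array(rnorm(78 * 96 * 66), c(78, 96, 66)), c(2, 2, 2))
  pc6 <- patchify(v, 6, 6)
  expect_equal(prod(pc6$grid), 13 * 16 * 11)  # 2,288 tokens
  expect_equal(nrow(pc6$patches), 2288)
  pc3 <- patchify(v, 6, 3)
  expect_equal(prod(pc3$grid), 25 * 31 * 21)  # 16,275 tokens
  expect_equal(nrow(pc3$patches), 16275)
  expect_equal(ncol(pc3$patches), 216)
  expect_error(patchify(v, 100, 6), "kernel exceeds volume")
})

test_that("stride = kernel partitions the grid without overlap", {
  v <- volume3d(array(1, c(12, 18, 6)), c(2, 2, 2))
  pc <- patchify(v, 6, 6)
  cover <- array(0, dim(v$data))
  k <- pc$kernel - 1
  for (p in seq_len(nrow(pc$origins))) {
    o <- pc$origins[p, ]
    cover[o[1]:(o[1] + k), o[2]:(o[2] + k), o[3]:(o[3] + k)] <-
      cover[o[1]:(o[1] + k), o[2]:(o[2] + k), o[3]:(o[3] + k)] + 1
  }
  expect_true(all(cover == 1))
})

test_that("patch content matches direct sub-block extraction", {
  set.seed(3)
  v <- volume3d(array(rnorm(12 * 12 * 12), c(12, 12, 12)), c(2, 2, 2))
  pc <- patchify(v, 6, 6)
  expect_equal(pc$patches[1, ], as.numeric(v$data[1:6, 1:6, 1:6]))
  o <- pc$origins[nrow(pc$origins), ]
  expect_equal(pc$patches[nrow(pc$patches), ],
               as.numeric(v$data[o[1]:(o[1] + 5), o[2]:(o[2] + 5),
                                 o[3]:(o[3] + 5)]))
})

test_that("encoder config enforces stride, heads, and token bookkeeping", {
  cfg <- global_net_config(c(30, 36, 30), 6, 6, 32, 2, 4, 16)
  expect_equal(cfg$n_patches, 5L * 6L * 5L)
  expect_equal(cfg$n_tokens, cfg$n_patches + 1L)
  expect_error(global_net_config(patch_stride = 7), "stride")
  expect_error(global_net_config(embed_dim = 30, heads = 4), "divisible")
})

test_that("attention rows are stochastic and latents carry the naming scheme", {
  cfg <- global_net_config(c(18, 18, 18), 6, 6, embed_dim = 16, depth = 2,
                           heads = 2, latent_dim = 64)
  net <- build_global_encoder(cfg, 2)
  v <- volume3d(array(rnorm(18^3), c(18, 18, 18)), c(2, 2, 2))
  fw <- petfusion:::forward_global(net, v, keep_attention = TRUE)
  for (A in fw$attention) for (h in seq_len(dim(A)[3]))
    expect_equal(rowSums(A[, , h]), rep(1, nrow(A)), tolerance = 1e-9)
  lat <- extract_global_latents(net, v)
  expect_length(lat, 64)
  expect_true("Global_latent_43" %in% names(lat))
  expect_identical(lat, extract_global_latents(net, v))
})

test_that("the context output is invariant to patch-token permutation", {
  cfg <- global_net_config(c(12, 12, 12), 6, 6, embed_dim = 16, depth = 2,
                           heads = 2, latent_dim = 8)
  net <- build_global_encoder(cfg, 5)
  v <- volume3d(array(rnorm(12^3), c(12, 12, 12)), c(2, 2, 2))
  emb <- petfusion:::embed_tokens(net, v)
  out1 <- petfusion:::encoder_forward(net, emb$tokens)
  perm <- c(1, 1 + sample(nrow(emb$tokens) - 1))
  out2 <- petfusion:::encoder_forward(net, emb$tokens[perm, ])
  expect_equal(out2$final[1, ], out1$final[1, ], tolerance = 1e-10)
})

test_that("zero embeddings and positions give a zero latent", {
  cfg <- global_net_config(c(12, 12, 12), 6, 6, embed_dim = 16, depth = 2,
                           heads = 2, latent_dim = 8)
  net <- build_global_encoder(cfg, 6)
  net$params$embed$W[] <- 0
  net$params$embed$b[] <- 0
  net$params$pos[] <- 0
  net$params$lnf$b[] <- 0
  net$params$lat$b[] <- 0
  v <- volume3d(array(rnorm(12^3), c(12, 12, 12)), c(2, 2, 2))
  lat <- extract_global_latents(net, v)
  expect_true(all(abs(lat) < 1e-8))
})

test_that("attention rollout obeys its closed forms", {
  n <- 5
  I5 <- diag(n)
  expect_equal(attention_rollout(list(I5, I5, I5)), I5)
  set.seed(9)
  A <- matrix(runif(n * n), n, n)
  A <- A / rowSums(A)
  R1 <- attention_rollout(list(A))
  expect_equal(R1, (A + I5) / rowSums(A + I5), tolerance = 1e-12)
  # two uniform layers: each residual-adjusted layer is (U + I)/2 and
  # U %*% U = U, so the rollout collapses to (3U + I)/4
  U <- matrix(1 / n, n, n)
  RU <- attention_rollout(list(U, U))
  expect_equal(RU, (3 * U + I5) / 4, tolerance = 1e-12)
  expect_equal(rowSums(RU), rep(1, n), tolerance = 1e-12)
  expect_error(attention_rollout(list(matrix(1, 2, 3))), "square")
  expect_error(attention_rollout(list(matrix(2, 2, 2))), "sum to 1")
})

test_that("rollout equals the brute-force matrix-chain oracle", {
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    stack <- lapply(1:3, function(l) {
      A <- array(runif(5 * 5 * 2), c(5, 5, 2))
      for (h in 1:2) A[, , h] <- A[, , h] / rowSums(A[, , h])
      A
    })
    R <- attention_rollout(stack)
    # oracle: explicit chain product of row-normalized head means + identity
    mats <- lapply(stack, function(A) {
      m <- (A[, , 1] + A[, , 2]) / 2 + diag(5)
      m / rowSums(m)
    })
    Rref <- mats[[3]] %*% mats[[2]] %*% mats[[1]]
    worst <- max(worst, max(abs(R - Rref)))
    expect_equal(rowSums(R), rep(1, 5), tolerance = 1e-12)
  }
  expect_lt(worst, 1e-10)
})

test_that("rollout maps live in [0,1] and degenerate nets give flat maps", {
  cfg <- global_net_config(c(12, 12, 12), 6, 6, embed_dim = 16, depth = 2,
                           heads = 2, latent_dim = 8)
  net <- build_global_encoder(cfg, 7)
  v <- volume3d(array(rnorm(12^3), c(12, 12, 12)), c(2, 2, 2))
  m <- rollout_map(net, v)
  expect_gte(min(m$data), 0)
  expect_lte(max(m$data), 1)
  # identical tokens force uniform attention, hence a constant painted map
  net$params$embed$W[] <- 0
  net$params$pos[] <- 0
  m0 <- rollout_map(net, v)
  expect_true(all(m0$data == m0$data[1]))
})

test_that("global channel training reduces loss and is seed-deterministic", {
  set.seed(12)
  cfg <- global_net_config(c(12, 12, 12), 6, 6, embed_dim = 8, depth = 1,
                           heads = 2, latent_dim = 4,
                           classes = c("IPD", "MSA", "PSP"))
  vols <- lapply(1:12, function(i) {
    a <- array(rnorm(12^3, 0, 0.3), c(12, 12, 12))
    cl <- ((i - 1) %% 3) + 1
    a[, (cl * 3 - 2):(cl * 3), ] <- a[, (cl * 3 - 2):(cl * 3), ] + 1.5
    a
  })
  labs <- c("IPD", "MSA", "PSP")[((1:12 - 1) %% 3) + 1]
  net <- build_global_encoder(cfg, 8)
  tr <- train_network(net, vols, labs,
                      list(epochs = 15, lr = 3e-3, batch_size = 6, seed = 3))
  expect_lt(tail(tr$log$train_loss, 1), tr$log$train_loss[1])
  tr2 <- train_network(net, vols, labs,
                       list(epochs = 15, lr = 3e-3, batch_size = 6,
                            seed = 3))
  expect_identical(tr$log, tr2$log)
})
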