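#' Global channel configuration
#'
#' A 3D patch-embedding Transformer encoder. The volume is resized to the
#' configured input shape, divided into (possibly overlapping) cubic patches
#' by a convolutional kernel, and linearly embedded. A pooled context token
#' — the global average of the patch embeddings — is prepended to the patch
#' sequence, learned positional encodings are added, and the sequence runs
#' through a pre-layer-norm Transformer encoder. The latent head reads the
#' context token; per-layer per-head attention matrices are exposed for
#' rollout attribution.
#'
#' @param input_shape Grid the channel operates on (volumes are resized to
#'   it). Default 78x96x66.
#' @param patch_kernel Cubic patch edge in voxels (default 6).
#' @param patch_stride Patch stride; stride < kernel gives overlapping
#'   patches (default 3), stride = kernel a partition.
#' @param embed_dim Token dimension (divisible by `heads`).
#' @param depth Number of encoder layers.
#' @param heads Attention heads per layer.
#' @param latent_dim Latent feature dimension read off the context token.
#' @param mlp_ratio Feed-forward expansion factor.
#' @param classes Class labels of the softmax head.
#' @return Object of class `pf_global_config`.
#' @export
global_net_config <- function(input_shape = c(78, 96, 66), patch_kernel = 6,
                              patch_stride = 3, embed_dim = 64, depth = 4,
                              heads = 4, latent_dim = 64, mlp_ratio = 2,
                              classes = c("IPD", "MSA", "PSP")) {
  if (patch_stride > patch_kernel) stop("stride must not exceed kernel")
  if (embed_dim %% heads != 0) stop("embed_dim must be divisible by heads")
  if (any((input_shape - patch_kernel) < 0)) stop("kernel exceeds volume")
  np <- prod(floor((input_shape - patch_kernel) / patch_stride) + 1)
  structure(list(input_shape = as.integer(input_shape),
                 patch_kernel = as.integer(patch_kernel),
                 patch_stride = as.integer(patch_stride),
                 embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth), heads = as.integer(heads),
                 latent_dim = as.integer(latent_dim),
                 mlp_ratio = mlp_ratio, n_patches = as.integer(np),
                 n_tokens = as.integer(np + 1), classes = classes),
            class = "pf_global_config")
}

#' Desk-scale global channel preset
#' @inheritParams global_net_config
#' @export
desk_global_config <- function(input_shape = c(30, 36, 30),
                               classes = c("IPD", "MSA", "PSP")) {
  global_net_config(input_shape, patch_kernel = 6, patch_stride = 6,
                    embed_dim = 32, depth = 2, heads = 4, latent_dim = 16,
                    classes = classes)
}

#' Divide a volume into embedded patch windows
#'
#' Sliding cubic windows of edge `kernel` at the given stride; token count
#' per axis is `floor((size - kernel) / stride) + 1`. Each token's voxel
#' footprint is recorded for mapping attention scores back to the grid.
#'
#' @param volume A [volume3d()] or 3D array already at the target shape.
#' @param kernel Patch edge length (voxels).
#' @param stride Step between patch origins.
#' @return List: `patches` (n_patches x kernel^3 matrix), `grid` (tokens per
#'   axis), `origins` (n_patches x 3, 1-based), `kernel`, `dims`.
#' @export
patchify <- function(volume, kernel, stride) {
  x <- as_input_array(volume)
  dims <- dim(x)
  if (any(kernel > dims)) stop("kernel exceeds volume")
  starts <- lapply(dims, function(s) seq(1L, s - kernel + 1L, by = stride))
  grid <- vapply(starts, length, 0L)
  ox <- rep(starts[[1]], times = grid[2] * grid[3])
  oy <- rep(rep(starts[[2]], each = grid[1]), times = grid[3])
  oz <- rep(starts[[3]], each = grid[1] * grid[2])
  off <- as.vector(outer(outer(0:(kernel - 1),
                               (0:(kernel - 1)) * dims[1], `+`),
                         (0:(kernel - 1)) * dims[1] * dims[2], `+`))
  origins_lin <- (ox - 1) + (oy - 1) * dims[1] + (oz - 1) * dims[1] * dims[2]
  idx <- outer(origins_lin, off, `+`) + 1L
  patches <- matrix(x[idx], nrow = length(origins_lin))
  list(patches = patches, grid = grid,
       origins = cbind(ox, oy, oz), kernel = kernel, dims = dims)
}

#' Build the global Transformer encoder
#'
#' Seeded initialization: Xavier-scaled attention and projection weights,
#' positional encodings ~ N(0, 0.02).
#'
#' @param config A [global_net_config()].
#' @param seed Integer seed.
#' @return Object of class `pf_global_net`.
#' @export
build_global_encoder <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  D <- config$embed_dim
  Dm <- as.integer(round(D * config$mlp_ratio))
  k3 <- config$patch_kernel^3
  mat <- function(nr, nc, sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)
  layers <- lapply(seq_len(config$depth), function(l) list(
    ln1 = list(g = rep(1, D), b = numeric(D)),
    Wq = mat(D, D, sqrt(1 / D)), bq = numeric(D),
    Wk = mat(D, D, sqrt(1 / D)), bk = numeric(D),
    Wv = mat(D, D, sqrt(1 / D)), bv = numeric(D),
    Wo = mat(D, D, sqrt(1 / D)), bo = numeric(D),
    ln2 = list(g = rep(1, D), b = numeric(D)),
    W1 = mat(D, Dm, sqrt(2 / D)), b1 = numeric(Dm),
    W2 = mat(Dm, D, sqrt(1 / Dm)), b2 = numeric(D)))
  params <- list(
    embed = list(W = mat(k3, D, sqrt(1 / k3)), b = numeric(D)),
    pos = mat(config$n_tokens, D, 0.02),
    layers = layers,
    lnf = list(g = rep(1, D), b = numeric(D)),
    lat = list(W = mat(D, config$latent_dim, sqrt(1 / D)),
               b = numeric(config$latent_dim)),
    head = list(W = mat(config$latent_dim, length(config$classes),
                        sqrt(1 / config$latent_dim)),
                b = numeric(length(config$classes))))
  structure(list(config = config, params = params,
                 n_params = sum(rapply(params, length, how = "unlist")),
                 trained = FALSE, seed = as.integer(seed)),
            class = "pf_global_net")
}

#' @export
print.pf_global_net <- function(x, ...) {
  cat(sprintf(
    "<pf_global_net> %d tokens (+ctx), embed %d, depth %d, heads %d%s\n",
    x$config$n_patches, x$config$embed_dim, x$config$depth, x$config$heads,
    if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  istd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * istd
  list(y = sweep(xhat * g[col(xhat)], 2, b, `+`),
       xhat = xhat, istd = istd)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * g[col(dy)]
  d <- ncol(dy)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$istd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# Token sequence for one volume: [context ; patches] embedding + positions.
embed_tokens <- function(net, volume) {
  cfg <- net$config
  x <- as_input_array(volume)
  if (!identical(dim(x), cfg$input_shape)) {
    vol <- if (inherits(volume, "pf_volume")) volume else volume3d(x)
    x <- resize_volume(vol, cfg$input_shape)$data
  }
  pc <- patchify(x, cfg$patch_kernel, cfg$patch_stride)
  pemb <- pc$patches %*% net$params$embed$W
  pemb <- sweep(pemb, 2, net$params$embed$b, `+`)
  ctx <- colMeans(pemb)
  tokens <- rbind(ctx, pemb, deparse.level = 0) + net$params$pos
  list(tokens = tokens, patch = pc, pemb_rows = nrow(pemb))
}

# Encoder forward with caches for backprop and the per-layer attention
# stacks (n_tokens x n_tokens x heads).
encoder_forward <- function(net, tokens, keep_attention = FALSE,
                            keep_cache = FALSE) {
  cfg <- net$config
  H <- cfg$heads
  dh <- cfg$embed_dim / H
  x <- tokens
  attn <- list()
  caches <- list()
  for (li in seq_len(cfg$depth)) {
    P <- net$params$layers[[li]]
    l1 <- ln_fwd(x, P$ln1$g, P$ln1$b)
    h <- l1$y
    Q <- sweep(h %*% P$Wq, 2, P$bq, `+`)
    K <- sweep(h %*% P$Wk, 2, P$bk, `+`)
    V <- sweep(h %*% P$Wv, 2, P$bv, `+`)
    n <- nrow(x)
    A <- array(0, c(n, n, H))
    O <- matrix(0, n, cfg$embed_dim)
    for (hd in seq_len(H)) {
      ix <- ((hd - 1) * dh + 1):(hd * dh)
      S <- Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) / sqrt(dh)
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A[, , hd] <- E / rowSums(E)
      O[, ix] <- A[, , hd] %*% V[, ix, drop = FALSE]
    }
    ao <- sweep(O %*% P$Wo, 2, P$bo, `+`)
    xm <- x + ao
    l2 <- ln_fwd(xm, P$ln2$g, P$ln2$b)
    pre <- sweep(l2$y %*% P$W1, 2, P$b1, `+`)
    relu <- pmax(pre, 0)
    x <- xm + sweep(relu %*% P$W2, 2, P$b2, `+`)
    if (keep_attention) attn[[li]] <- A
    if (keep_cache)
      caches[[li]] <- list(l1 = l1, Q = Q, K = K, V = V, A = A, O = O,
                           x_in = tokens, xm = xm, l2 = l2, pre = pre,
                           relu = relu)
  }
  lf <- ln_fwd(x, net$params$lnf$g, net$params$lnf$b)
  list(x = x, final = lf$y, lnf_cache = lf, attention = attn,
       caches = caches)
}

forward_global <- function(net, volume, keep_attention = FALSE,
                           keep_cache = FALSE) {
  emb <- embed_tokens(net, volume)
  enc <- encoder_forward(net, emb$tokens, keep_attention, keep_cache)
  latent <- drop(enc$final[1, ] %*% net$params$lat$W) + net$params$lat$b
  logits <- drop(latent %*% net$params$head$W) + net$params$head$b
  c(enc, list(latent = latent, logits = logits,
              probs = nn_softmax(logits), emb = emb))
}

global_fwd_bwd <- function(net, x, y_onehot, loss_only = FALSE) {
  cfg <- net$config
  fw <- forward_global(net, x, keep_attention = FALSE,
                       keep_cache = !loss_only)
  loss <- -sum(y_onehot * log(pmax(fw$probs, 1e-12)))
  if (loss_only) return(list(loss = loss))
  H <- cfg$heads
  dh <- cfg$embed_dim / H
  dlogits <- fw$probs - y_onehot
  ghead <- list(W = outer(fw$latent, dlogits), b = dlogits)
  dlatent <- drop(net$params$head$W %*% dlogits)
  glat <- list(W = outer(fw$final[1, ], dlatent), b = dlatent)
  dfinal <- matrix(0, nrow(fw$final), ncol(fw$final))
  dfinal[1, ] <- drop(net$params$lat$W %*% dlatent)
  bf <- ln_bwd(dfinal, fw$lnf_cache, net$params$lnf$g)
  glnf <- list(g = bf$dg, b = bf$db)
  dx <- bf$dx
  glayers <- vector("list", cfg$depth)
  for (li in rev(seq_len(cfg$depth))) {
    P <- net$params$layers[[li]]
    cc <- fw$caches[[li]]
    # MLP block
    dW2 <- t(cc$relu) %*% dx
    db2 <- colSums(dx)
    dpre <- (dx %*% t(P$W2)) * (cc$pre > 0)
    dW1 <- t(cc$l2$y) %*% dpre
    db1 <- colSums(dpre)
    b2l <- ln_bwd(dpre %*% t(P$W1), cc$l2, P$ln2$g)
    dxm <- dx + b2l$dx
    # attention block
    dWo <- t(cc$O) %*% dxm
    dbo <- colSums(dxm)
    dO <- dxm %*% t(P$Wo)
    dQ <- matrix(0, nrow(dO), cfg$embed_dim)
    dK <- dQ; dV <- dQ
    for (hd in seq_len(H)) {
      ix <- ((hd - 1) * dh + 1):(hd * dh)
      A <- cc$A[, , hd]
      dOh <- dO[, ix, drop = FALSE]
      dA <- dOh %*% t(cc$V[, ix, drop = FALSE])
      dV[, ix] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, ix] <- dS %*% cc$K[, ix, drop = FALSE] / sqrt(dh)
      dK[, ix] <- t(dS) %*% cc$Q[, ix, drop = FALSE] / sqrt(dh)
    }
    h <- cc$l1$y
    gl <- list(
      ln1 = NULL,
      Wq = t(h) %*% dQ, bq = colSums(dQ),
      Wk = t(h) %*% dK, bk = colSums(dK),
      Wv = t(h) %*% dV, bv = colSums(dV),
      Wo = dWo, bo = dbo,
      ln2 = list(g = b2l$dg, b = b2l$db),
      W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    dhh <- dQ %*% t(P$Wq) + dK %*% t(P$Wk) + dV %*% t(P$Wv)
    b1l <- ln_bwd(dhh, cc$l1, P$ln1$g)
    gl$ln1 <- list(g = b1l$dg, b = b1l$db)
    dx <- dxm + b1l$dx
    glayers[[li]] <- gl
  }
  # embedding: tokens = rbind(ctx, pemb) + pos; ctx = colMeans(pemb)
  dpos <- dx
  np <- fw$emb$pemb_rows
  dpemb <- dx[-1, , drop = FALSE] +
    matrix(dx[1, ] / np, np, ncol(dx), byrow = TRUE)
  gembed <- list(W = t(fw$emb$patch$patches) %*% dpemb, b = colSums(dpemb))
  list(loss = loss,
       grads = list(embed = gembed, pos = dpos, layers = glayers,
                    lnf = glnf, lat = glat, head = ghead))
}

#' @rdname train_network
#' @export
train_network.pf_global_net <- function(network, volumes, labels,
                                        train_config = list()) {
  check_training_inputs(network, volumes, labels)
  tc <- resolve_train_config(train_config)
  nn_fit_loop(network, volumes, labels, tc, global_fwd_bwd)
}

#' Extract global-channel latent features
#'
#' The context-token representation after the final encoder layer, passed
#' through the latent head and named `Global_latent_0 .. Global_latent_(D-1)`.
#'
#' @param trained A (trained) `pf_global_net`.
#' @param volume A z-scored [volume3d()] or 3D array.
#' @return Named numeric latent vector.
#' @export
extract_global_latents <- function(trained, volume) {
  lat <- forward_global(trained, volume)$latent
  names(lat) <- paste0("Global_latent_", seq_along(lat) - 1L)
  lat
}

#' Attention rollout
#'
#' Per layer, attention matrices are averaged over heads, a residual
#' identity is added and rows renormalized; the rollout is the reverse-order
#' matrix product `R = A_L ... A_1`, itself row-stochastic, tracing
#' token-to-token influence through the encoder.
#'
#' @param stack List over layers of attention arrays
#'   (tokens x tokens x heads) or matrices, each row-stochastic.
#' @return Row-stochastic rollout matrix.
#' @export
attention_rollout <- function(stack) {
  if (!length(stack)) stop("empty attention stack")
  mats <- lapply(stack, function(A) {
    m <- if (length(dim(A)) == 3) apply(A, c(1, 2), mean) else as.matrix(A)
    if (nrow(m) != ncol(m)) stop("attention matrices must be square")
    if (max(abs(rowSums(m) - 1)) > 1e-6)
      stop("attention rows must sum to 1")
    m <- m + diag(nrow(m))
    m / rowSums(m)
  })
  n <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != n))
    stop("inconsistent token count across layers")
  R <- diag(n)
  for (m in mats) R <- m %*% R
  R
}

#' Rollout attention map
#'
#' Computes the attention rollout for a volume, takes the context-token row
#' over patch tokens, and paints each token's score uniformly over its voxel
#' footprint (overlapping footprints are averaged). The map is resized to
#' the original volume geometry and min-max normalized to [0, 1].
#'
#' @param trained A trained `pf_global_net`.
#' @param volume Input [volume3d()].
#' @return `pf_attribution` with `source = "rollout"`.
#' @export
rollout_map <- function(trained, volume) {
  cfg <- trained$config
  fw <- forward_global(trained, volume, keep_attention = TRUE)
  R <- attention_rollout(fw$attention)
  score <- R[1, -1]
  pc <- fw$emb$patch
  acc <- array(0, pc$dims)
  cnt <- array(0, pc$dims)
  k <- pc$kernel - 1L
  for (p in seq_along(score)) {
    o <- pc$origins[p, ]
    sel <- list(o[1]:(o[1] + k), o[2]:(o[2] + k), o[3]:(o[3] + k))
    acc[sel[[1]], sel[[2]], sel[[3]]] <-
      acc[sel[[1]], sel[[2]], sel[[3]]] + score[p]
    cnt[sel[[1]], sel[[2]], sel[[3]]] <-
      cnt[sel[[1]], sel[[2]], sel[[3]]] + 1
  }
  m <- acc
  m[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  odim <- dim(as_input_array(volume))
  if (!identical(dim(m), odim)) m <- resize_trilinear(m, odim)
  m <- pmax(m, 0)
  attribution_volume(m, spacing_of(volume), "context", "rollout")
}
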