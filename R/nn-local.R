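#' Local channel configuration
#'
#' A three-layer dilated 3D convolutional encoder: 3x3x3 kernels with
#' strictly increasing dilation rates, ReLU nonlinearities, "same" zero
#' padding (spatial resolution is maintained throughout), global average
#' pooling of the last feature map as the latent vector, and a softmax
#' classification head. The default mirrors the clinical-scale architecture
#' (32/64/128 filters, dilations 1/2/3 on a 79x95x69 grid); the desk preset
#' ([desk_local_config()]) shrinks filters so tests train on one CPU.
#'
#' @param input_shape Expected input grid (the encoder itself is fully
#'   convolutional and accepts any shape).
#' @param filters Filters per layer (latent dimension = last entry).
#' @param dilations Strictly increasing dilation rates.
#' @param classes Class labels for the softmax head.
#' @return Object of class `pf_local_config`.
#' @export
local_net_config <- function(input_shape = c(79, 95, 69),
                             filters = c(32, 64, 128),
                             dilations = c(1, 2, 3),
                             classes = c("IPD", "MSA", "PSP")) {
  if (length(filters) != length(dilations))
    stop("filters and dilations must have equal length")
  if (any(diff(dilations) <= 0)) stop("dilations must be strictly increasing")
  rf <- 1L + 2L * sum(dilations)
  if (any(input_shape < rf))
    stop("input smaller than receptive field (", rf, " voxels)")
  structure(list(input_shape = as.integer(input_shape),
                 filters = as.integer(filters),
                 dilations = as.integer(dilations),
                 latent_dim = as.integer(filters[length(filters)]),
                 classes = classes),
            class = "pf_local_config")
}

#' Desk-scale local channel preset
#' @inheritParams local_net_config
#' @export
desk_local_config <- function(input_shape = c(32, 36, 32),
                              classes = c("IPD", "MSA", "PSP")) {
  local_net_config(input_shape, filters = c(4, 8, 16),
                   dilations = c(1, 2, 3), classes = classes)
}

#' Build the local dilated-convolution encoder
#'
#' Seeded He-normal initialization; biases start at zero. The effective
#' receptive field of the default three dilated layers is
#' `1 + 2*(d1 + d2 + d3)` voxels per axis (13 for dilations 1/2/3).
#'
#' @param config A [local_net_config()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `pf_local_net` with `params`, `config`,
#'   `n_params`.
#' @export
build_local_encoder <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  cins <- c(1L, config$filters[-length(config$filters)])
  conv <- Map(function(cin, cout) {
    list(W = matrix(rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))),
                    27 * cin, cout),
         b = numeric(cout))
  }, cins, config$filters)
  head <- list(W = matrix(rnorm(config$latent_dim * length(config$classes),
                                0, sqrt(1 / config$latent_dim)),
                          config$latent_dim, length(config$classes)),
               b = numeric(length(config$classes)))
  params <- list(conv = conv, head = head)
  n_params <- sum(rapply(params, length, how = "unlist"))
  structure(list(config = config, params = params, n_params = n_params,
                 trained = FALSE, seed = as.integer(seed)),
            class = "pf_local_net")
}

#' @export
print.pf_local_net <- function(x, ...) {
  cat(sprintf("<pf_local_net> filters %s, dilations %s, %d params%s\n",
              paste(x$config$filters, collapse = "/"),
              paste(x$config$dilations, collapse = "/"), x$n_params,
              if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}

#' Effective receptive field of the local encoder
#' @param config A [local_net_config()].
#' @return Receptive field extent in voxels along each axis.
#' @export
local_receptive_field <- function(config) {
  1L + 2L * sum(config$dilations)
}

# Forward pass. x: 3D array. Returns logits, probabilities, latent, and
# (if keep_acts) the post-ReLU feature maps per layer for attribution.
forward_local <- function(net, x, keep_acts = FALSE) {
  dims <- dim(x)
  a <- matrix(as.numeric(x), ncol = 1)
  acts <- list()
  pre <- list()
  for (l in seq_along(net$params$conv)) {
    z <- cpp_conv3d_fwd(a, dims, net$config$dilations[l],
                        net$params$conv[[l]]$W, net$params$conv[[l]]$b)
    a <- pmax(z, 0)
    if (keep_acts) {
      pre[[l]] <- z
      acts[[l]] <- a
    }
  }
  latent <- colMeans(a)
  ln <- latent_normalize(net, latent)
  logits <- drop(ln %*% net$params$head$W) + net$params$head$b
  list(logits = logits, probs = nn_softmax(logits), latent = latent,
       acts = acts, pre = pre, dims = dims, last = a)
}

# Forward + backward for one example; returns cross-entropy loss and
# gradients with the same structure as net$params.
local_fwd_bwd <- function(net, x, y_onehot, loss_only = FALSE) {
  dims <- dim(x)
  nl <- length(net$params$conv)
  a <- matrix(as.numeric(x), ncol = 1)
  inputs <- vector("list", nl)
  masks <- vector("list", nl)
  for (l in seq_len(nl)) {
    inputs[[l]] <- a
    z <- cpp_conv3d_fwd(a, dims, net$config$dilations[l],
                        net$params$conv[[l]]$W, net$params$conv[[l]]$b)
    masks[[l]] <- z > 0
    a <- pmax(z, 0)
  }
  latent <- colMeans(a)
  ln <- latent_normalize(net, latent)
  logits <- drop(ln %*% net$params$head$W) + net$params$head$b
  probs <- nn_softmax(logits)
  loss <- -sum(y_onehot * log(pmax(probs, 1e-12)))
  if (loss_only) return(list(loss = loss))
  dlogits <- probs - y_onehot
  gh <- list(W = outer(ln, dlogits), b = dlogits)
  dlatent <- drop(net$params$head$W %*% dlogits) / latent_sd(net)
  nvox <- nrow(a)
  g <- matrix(dlatent, nvox, length(dlatent), byrow = TRUE) / nvox
  gconv <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    g <- g * masks[[l]]
    bw <- cpp_conv3d_bwd(inputs[[l]], dims, net$config$dilations[l],
                         net$params$conv[[l]]$W, g, l > 1L)
    gconv[[l]] <- list(W = bw$dW, b = drop(bw$db))
    if (l > 1L) g <- bw$din
  }
  list(loss = loss, grads = list(conv = gconv, head = gh),
       latent = latent)
}

# Latent standardization. Global average pooling over tens of thousands of
# voxels concentrates the latent distribution tightly around its mean, so
# the softmax head sees a z-scored latent; without this the class signal is
# orders of magnitude smaller than the latent offsets and the head cannot
# use it. The statistics are re-estimated over the training set at the
# start of every epoch (constant within an epoch, treated as constants in
# the backward pass) and frozen after training, so evaluation is
# deterministic.
latent_normalize <- function(net, latent) {
  if (is.null(net$latent_norm)) return(latent)
  (latent - net$latent_norm$mu) / net$latent_norm$sd
}

latent_sd <- function(net) {
  if (is.null(net$latent_norm)) 1 else net$latent_norm$sd
}

#' @rdname train_network
#' @export
train_network.pf_local_net <- function(network, volumes, labels,
                                       train_config = list()) {
  check_training_inputs(network, volumes, labels)
  tc <- resolve_train_config(train_config)
  refresh_norm <- function(net, vols) {
    lat <- t(vapply(vols, function(v)
      forward_local(net, as_input_array(v))$latent,
      numeric(net$config$latent_dim)))
    sds <- apply(lat, 2, sd)
    net$latent_norm <- list(mu = colMeans(lat),
                            sd = ifelse(sds > 0, sds, 1))
    net
  }
  network$latent_norm <- NULL
  network <- refresh_norm(network, volumes)
  # the softmax head trains at the configured rate; the convolutional body
  # drifts an order of magnitude slower so the frozen-per-epoch latent
  # statistics stay representative (body_lr_mult is configurable)
  mult <- tc$body_lr_mult %||% 0.05
  tc$lr <- list(conv = tc$lr * mult, head = tc$lr)
  nn_fit_loop(network, volumes, labels, tc, local_fwd_bwd,
              on_epoch = refresh_norm)
}

#' Extract local-channel latent features
#'
#' Global-average-pooled last-layer feature vector, named
#' `Local_latent_0 .. Local_latent_(D-1)`.
#'
#' @param trained A (trained) `pf_local_net`.
#' @param volume A z-scored [volume3d()] or 3D array.
#' @return Named numeric latent vector.
#' @export
extract_local_latents <- function(trained, volume) {
  lat <- forward_local(trained, as_input_array(volume))$latent
  names(lat) <- paste0("Local_latent_", seq_along(lat) - 1L)
  lat
}

#' Predict class probabilities from the local channel head
#' @param trained A trained `pf_local_net`.
#' @param volume Input volume or array.
#' @return Named probability vector over the configured classes.
#' @export
predict_local <- function(trained, volume) {
  p <- forward_local(trained, as_input_array(volume))$probs
  setNames(p, trained$config$classes)
}

#' Layer-CAM saliency map
#'
#' Class-activation mapping at a chosen convolutional layer:
#' `M = ReLU( sum_k ReLU(dy_c/dA_k) * A_k )` where `A_k` are the layer's
#' post-ReLU feature maps and the gradient is of the target-class logit.
#' Because the encoder maintains spatial resolution, the map is already in
#' input geometry; it is min-max normalized to [0, 1].
#'
#' @param trained A trained `pf_local_net`.
#' @param volume Input volume (z-scored) or 3D array.
#' @param target_class Class label or index to explain.
#' @param layer Conv layer index (default: last).
#' @return Object of class `pf_attribution`: a [volume3d()] grid in `[0,1]`
#'   plus `class` and `source = "layer_cam"`.
#' @export
layer_cam <- function(trained, volume, target_class,
                      layer = length(trained$params$conv)) {
  x <- as_input_array(volume)
  dims <- dim(x)
  nl <- length(trained$params$conv)
  if (!(layer %in% seq_len(nl))) stop("unknown layer: ", layer)
  cls <- if (is.character(target_class))
    match(target_class, trained$config$classes) else as.integer(target_class)
  if (is.na(cls) || cls < 1 || cls > length(trained$config$classes))
    stop("class index out of range")
  a <- matrix(as.numeric(x), ncol = 1)
  inputs <- list(); masks <- list(); acts <- list()
  for (l in seq_len(nl)) {
    inputs[[l]] <- a
    z <- cpp_conv3d_fwd(a, dims, trained$config$dilations[l],
                        trained$params$conv[[l]]$W,
                        trained$params$conv[[l]]$b)
    masks[[l]] <- z > 0
    a <- pmax(z, 0)
    acts[[l]] <- a
  }
  # gradient of the class logit wrt the chosen layer's activations
  dlatent <- trained$params$head$W[, cls] / latent_sd(trained)
  nvox <- nrow(a)
  g <- matrix(dlatent, nvox, length(dlatent), byrow = TRUE) / nvox
  l <- nl
  while (l > layer) {
    g <- g * masks[[l]]
    bw <- cpp_conv3d_bwd(inputs[[l]], dims, trained$config$dilations[l],
                         trained$params$conv[[l]]$W, g, TRUE)
    g <- bw$din
    l <- l - 1L
  }
  m <- rowSums(pmax(g, 0) * acts[[layer]])
  m <- pmax(m, 0)
  attribution_volume(array(m, dims), spacing_of(volume),
                     trained$config$classes[cls], "layer_cam")
}

spacing_of <- function(volume) {
  if (inherits(volume, "pf_volume")) volume$spacing else c(1, 1, 1)
}

#' Construct an attribution volume (non-negative, min-max scaled to [0,1])
#' @param data Non-negative 3D array.
#' @param spacing Voxel spacing.
#' @param class Class label the map explains.
#' @param source `"layer_cam"` or `"rollout"`.
#' @return `pf_attribution`, which is also a valid `pf_volume`.
#' @export
attribution_volume <- function(data, spacing, class, source) {
  if (any(data < 0)) stop("attribution values must be non-negative")
  rng <- range(data)
  data <- if (diff(rng) > 0) (data - rng[1]) / diff(rng) else data * 0
  v <- volume3d(data, spacing, array(TRUE, dim(data)))
  structure(c(v, list(class = class, source = source)),
            class = c("pf_attribution", "pf_volume"))
}
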