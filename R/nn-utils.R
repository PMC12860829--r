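# Shared neural-network machinery: initialization, Adam, softmax losses.
# Parameters and gradients are nested lists of matrices/vectors with
# identical structure, so the optimizer can walk them generically.

nn_softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

nn_onehot <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

# `lr` may be a scalar or a nested list mirroring (a prefix of) the
# parameter tree, so parameter groups can train at different rates.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  walk <- function(p, g, m, v, lr) {
    if (is.list(p)) {
      lrs <- if (is.list(lr)) lr else
        setNames(rep(list(lr), length(p)), names(p))
      out <- Map(walk, p, g, m, v, lrs)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      lr1 <- if (is.list(lr)) lr[[1]] else lr
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr1 * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v, lr)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

grad_accumulate <- function(acc, g, w = 1) {
  if (is.null(acc)) {
    if (is.list(g)) return(lapply(g, grad_accumulate, acc = NULL, w = w))
    return(g * w)
  }
  if (is.list(g)) return(Map(grad_accumulate, acc, g, MoreArgs = list(w = w)))
  acc + g * w
}

grad_scale <- function(g, w) {
  if (is.list(g)) lapply(g, grad_scale, w = w) else g * w
}

# Global-norm gradient clipping: rescale the whole gradient pytree when its
# L2 norm exceeds `max_norm`.
grad_clip <- function(g, max_norm) {
  nrm <- sqrt(sum(rapply(g, function(x) sum(x^2), how = "unlist")))
  if (is.finite(nrm) && nrm > max_norm) g <- grad_scale(g, max_norm / nrm)
  g
}

# Extract the 3D data array a training example, accepting volumes or arrays.
as_input_array <- function(x) {
  if (inherits(x, "pf_volume")) x$data else x
}

#' Train a neural channel
#'
#' Generic seeded trainer shared by the local (dilated convolutional) and
#' global (Transformer) channels: cross-entropy loss, Adam updates,
#' mini-batches, optional early stopping on a held-out validation fraction.
#' Deterministic given the seed.
#'
#' @param network A built (untrained) network object.
#' @param volumes List of z-scored input volumes (or 3D arrays).
#' @param labels Character vector of diagnosis labels per volume.
#' @param train_config List: `epochs` (default 50), `lr` (1e-3),
#'   `batch_size` (8), `seed` (1), `val_fraction` (0 = no early stopping),
#'   `patience` (5), `clip` (global-norm gradient clip, default 5).
#' @return The trained network, with `$log` holding per-epoch losses.
#' @export
train_network <- function(network, volumes, labels,
                          train_config = list()) {
  UseMethod("train_network")
}

resolve_train_config <- function(tc) {
  modifyList(list(epochs = 50L, lr = 1e-3, batch_size = 8L, seed = 1L,
                  val_fraction = 0, patience = 5L, clip = 5,
                  verbose = FALSE), tc)
}

check_training_inputs <- function(network, volumes, labels) {
  if (length(unique(labels)) < 2) stop("need at least 2 classes to train")
  if (length(volumes) != length(labels)) stop("volumes/labels length mismatch")
  if (!all(labels %in% network$config$classes))
    stop("labels outside the network's class set")
}

# Shared mini-batch Adam loop; fwd_bwd(net, x, y_onehot) must return
# list(loss, grads). `on_batch(network, fbs)`, when given, can update
# network state (e.g. running normalization statistics) after each step.
nn_fit_loop <- function(network, volumes, labels, tc, fwd_bwd,
                        on_batch = NULL, on_epoch = NULL) {
  classes <- network$config$classes
  y <- nn_onehot(labels, classes)
  set.seed(as.integer(tc$seed))
  n <- length(volumes)
  idx <- sample(n)
  n_val <- floor(tc$val_fraction * n)
  val_idx <- if (n_val >= 1) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  state <- adam_init(network$params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  best <- list(loss = Inf, params = network$params, wait = 0L)
  for (ep in seq_len(tc$epochs)) {
    if (!is.null(on_epoch)) network <- on_epoch(network, volumes[tr_idx])
    ord <- sample(tr_idx)
    ep_loss <- 0
    for (b0 in seq(1, length(ord), by = tc$batch_size)) {
      bidx <- ord[b0:min(length(ord), b0 + tc$batch_size - 1L)]
      acc <- NULL
      bloss <- 0
      fbs <- vector("list", length(bidx))
      for (k in seq_along(bidx)) {
        fb <- fwd_bwd(network, as_input_array(volumes[[bidx[k]]]),
                      y[bidx[k], ])
        bloss <- bloss + fb$loss
        acc <- grad_accumulate(acc, fb$grads, 1 / length(bidx))
        fbs[[k]] <- fb
      }
      ep_loss <- ep_loss + bloss
      if (is.finite(tc$clip)) acc <- grad_clip(acc, tc$clip)
      upd <- adam_step(network$params, acc, state, lr = tc$lr)
      network$params <- upd$params
      state <- upd$state
      if (!is.null(on_batch)) network <- on_batch(network, fbs)
    }
    ep_loss <- ep_loss / length(tr_idx)
    vloss <- NA_real_
    if (length(val_idx)) {
      vloss <- mean(vapply(val_idx, function(i)
        fwd_bwd(network, as_input_array(volumes[[i]]), y[i, ],
                loss_only = TRUE)$loss, 0))
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = network$params, wait = 0L)
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= tc$patience) {
          log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss,
                                       val_loss = vloss))
          network$params <- best$params
          break
        }
      }
    }
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss,
                                 val_loss = vloss))
    if (isTRUE(tc$verbose))
      message(sprintf("epoch %d: train %.4f val %.4f", ep, ep_loss, vloss))
  }
  if (length(val_idx) && best$loss < Inf) network$params <- best$params
  network$trained <- TRUE
  network$log <- log
  network$train_seed <- as.integer(tc$seed)
  network
}
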