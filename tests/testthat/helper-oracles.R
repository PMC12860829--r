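# Brute-force texture-matrix oracles, written independently of the package
# kernels: explicit pair/line/component enumeration in plain R over small
# level grids (0 = outside ROI, levels 1..ng).

DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0),
  c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1), c(1, 1, 1),
  c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

DIRS26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
DIRS26 <- DIRS26[rowSums(abs(DIRS26)) > 0, ]

in_bounds <- function(v, d) all(v >= 1) && all(v <= d)

oracle_glcm <- function(lev, ng) {
  d <- dim(lev)
  P <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l1 <- lev[x, y, z]
    if (l1 == 0) next
    for (k in 1:13) {
      v <- c(x, y, z) + DIRS13[k, ]
      if (!in_bounds(v, d)) next
      l2 <- lev[v[1], v[2], v[3]]
      if (l2 == 0) next
      P[l1, l2] <- P[l1, l2] + 1
      P[l2, l1] <- P[l2, l1] + 1
    }
  }
  P
}

# Runs via explicit line extraction and rle per direction.
oracle_glrlm <- function(lev, ng) {
  d <- dim(lev)
  counts <- list()
  add_run <- function(l, len) {
    key <- paste(l, len)
    counts[[key]] <<- (counts[[key]] %||% 0) + 1
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  coords <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
  for (k in 1:13) {
    dir <- DIRS13[k, ]
    # line id: project each voxel to its line origin
    starts <- coords[apply(coords, 1, function(v) {
      p <- v - dir
      !in_bounds(p, d)
    }), , drop = FALSE]
    for (s in seq_len(nrow(starts))) {
      v <- starts[s, ]
      vals <- integer(0)
      while (in_bounds(v, d)) {
        vals <- c(vals, lev[v[1], v[2], v[3]])
        v <- v + dir
      }
      r <- rle(vals)
      for (i in seq_along(r$lengths))
        if (r$values[i] > 0) add_run(r$values[i], r$lengths[i])
    }
  }
  maxlen <- max(vapply(names(counts),
                       function(k) as.integer(strsplit(k, " ")[[1]][2]), 0L))
  R <- matrix(0, ng, maxlen)
  for (k in names(counts)) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    R[ij[1], ij[2]] <- counts[[k]]
  }
  R
}

# Zones by repeated mask dilation (26-connectivity) per gray level.
oracle_glszm_zones <- function(lev) {
  d <- dim(lev)
  remaining <- lev > 0
  zones <- NULL
  while (any(remaining)) {
    seedv <- which(remaining, arr.ind = TRUE)[1, ]
    l <- lev[seedv[1], seedv[2], seedv[3]]
    comp <- array(FALSE, d)
    comp[seedv[1], seedv[2], seedv[3]] <- TRUE
    same <- lev == l & remaining
    repeat {
      grown <- comp
      for (k in seq_len(nrow(DIRS26))) {
        sh <- shift_array(comp, DIRS26[k, ])
        grown <- grown | (sh & same)
      }
      if (identical(grown, comp)) break
      comp <- grown
    }
    zones <- rbind(zones, c(l, sum(comp)))
    remaining[comp] <- FALSE
  }
  zones
}

shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- max(1, 1 + off[1]):min(d[1], d[1] + off[1])
  sy <- max(1, 1 + off[2]):min(d[2], d[2] + off[2])
  sz <- max(1, 1 + off[3]):min(d[3], d[3] + off[3])
  out[sx, sy, sz] <- a[sx - off[1], sy - off[2], sz - off[3]]
  out
}

oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  out <- matrix(0, ng, 2)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l <- lev[x, y, z]
    if (l == 0) next
    nb <- c()
    for (k in seq_len(nrow(DIRS26))) {
      v <- c(x, y, z) + DIRS26[k, ]
      if (!in_bounds(v, d)) next
      ln <- lev[v[1], v[2], v[3]]
      if (ln > 0) nb <- c(nb, ln)
    }
    if (length(nb)) {
      out[l, 1] <- out[l, 1] + 1
      out[l, 2] <- out[l, 2] + abs(l - mean(nb))
    }
  }
  out
}

oracle_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  D <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l <- lev[x, y, z]
    if (l == 0) next
    dep <- 1
    for (k in seq_len(nrow(DIRS26))) {
      v <- c(x, y, z) + DIRS26[k, ]
      if (!in_bounds(v, d)) next
      ln <- lev[v[1], v[2], v[3]]
      if (ln > 0 && abs(ln - l) <= alpha) dep <- dep + 1
    }
    D[l, dep] <- D[l, dep] + 1
  }
  D
}

# Random small discretized ROI: levels 0..ng over a <=6x6x6 grid with a
# random connected-ish mask.
random_level_grid <- function(seed, max_edge = 6L, ng = 4L) {
  set.seed(seed)
  d <- sample(2:max_edge, 3, replace = TRUE)
  lev <- array(sample(0:ng, prod(d), replace = TRUE,
                      prob = c(0.25, rep(0.75 / ng, ng))), d)
  if (all(lev == 0)) lev[1, 1, 1] <- 1L
  lev
}

trim_zero_cols <- function(m) {
  keep <- max(1L, max(which(colSums(m) > 0)))
  m[, seq_len(keep), drop = FALSE]
}
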