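# Shared small fixtures built in code.

tiny_volume <- function(seed = 1, d = c(8, 8, 8), spacing = c(2, 2, 2)) {
  set.seed(seed)
  volume3d(array(abs(rnorm(prod(d))) + 0.5, d), spacing)
}

# A discretized ROI wrapper around an arbitrary level grid so texture
# matrices can be computed on hand-built levels.
droi_from_levels <- function(lev, spacing = c(1, 1, 1), bin_width = 1) {
  lev <- array(as.integer(lev), dim(lev))
  structure(list(levels = lev, dims = dim(lev), ng = max(lev),
                 bin_width = bin_width,
                 values = as.numeric(lev[lev > 0]), spacing = spacing,
                 n_voxels = sum(lev > 0), mask = lev > 0),
            class = "pf_discrete_roi")
}

# Small single-region atlas on an arbitrary grid (label 1 = putamen).
one_region_atlas <- function(d = c(10, 10, 10), spacing = c(2, 2, 2)) {
  labels <- array(0L, d)
  labels[3:7, 3:7, 3:7] <- 1L
  structure(list(labels = labels, registry = c(`1` = "putamen"),
                 envelope = array(TRUE, d), spacing = spacing),
            class = "pf_atlas")
}

# Desk-scale phantom cohort shared across tests (cached per session).
desk_cohort <- local({
  cache <- list()
  function(n_per_class = 10, seed = 7, cohort_id = "testA",
           external = FALSE) {
    key <- paste(n_per_class, seed, cohort_id, external)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n <- c(IPD = n_per_class, MSA = n_per_class, PSP = n_per_class)
    sp <- if (external)
      phantom_spec_external(n, grid_shape = c(32, 36, 32),
                            spacing = c(4, 4, 4), cohort_id = cohort_id)
    else
      phantom_spec(n, grid_shape = c(32, 36, 32), spacing = c(4, 4, 4),
                   cohort_id = cohort_id)
    co <- simulate_cohort(sp, seed)
    cache[[key]] <<- co
    co
  }
})

# Tiny pipeline configuration for smoke/determinism tests.
tiny_pipeline_config <- function(seed = 11) {
  list(seed = seed,
       phantom = list(n_train_per_class = 8L, n_test_per_class = 4L),
       localnet = list(filters = c(2L, 4L, 6L), epochs = 1L,
                       n_net_train_per_class = 8L),
       globalnet = list(embed_dim = 16L, depth = 1L, heads = 2L,
                        latent_dim = 8L, epochs = 2L,
                        n_net_train_per_class = 8L),
       interpret = list(n_permutations = 10L, background_n = 15L,
                        instances_max = 6L),
       attribution = list(n_subjects = 4L))
}
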