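# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

# Small default-gain cohort used by several end-to-end tests.
small_cohort <- function() {
  cached("small_cohort", function() {
    cfg <- sim_config(grid_shape = c(12L, 12L, 6L), n_hc = 4L, n_sz = 4L,
                      n_timepoints = 120L, seed = 42L)
    coh <- generate_cohort(cfg)
    ials <- lapply(coh$subjects,
                   function(s) discretize_ial(zscore_voxels(s$series)))
    names(ials) <- coh$cohort$subject_id
    props <- lapply(ials, polarity_proportions)
    dpr <- fit_dpr(props, seed = 7L, replicates = 8L)
    list(cfg = cfg, cohort = coh$cohort, subjects = coh$subjects,
         ials = ials, props = props, dpr = dpr)
  })
}

# Three well-separated (h, l, n) blobs at the canonical regime centroids.
blob_props <- function(n_per = 150L, noise_sd = 0.01, seed = 5L) {
  centers <- rbind(c(0.46, 0.24, 0.30),
                   c(0.23, 0.46, 0.31),
                   c(0.33, 0.33, 0.34))
  set.seed(seed)
  x <- do.call(rbind, lapply(1:3, function(i) {
    pts <- matrix(rnorm(n_per * 2L, sd = noise_sd), n_per)
    cbind(centers[i, 1] + pts[, 1], centers[i, 2] + pts[, 2])
  }))
  m <- cbind(x, 1 - rowSums(x))
  colnames(m) <- c("h", "l", "n")
  list(samples = m, truth = centers,
       membership = rep(1:3, each = n_per))
}

# Best permutation match between two centroid matrices (rows are clusters);
# small k, so exhaustive search over permutations is the oracle.
best_match_error <- function(est, truth) {
  k <- nrow(truth)
  perms <- permutations_of(k)
  errs <- apply(perms, 1L, function(p) max(abs(est[p, ] - truth)))
  min(errs)
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))
  }))
}
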