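#' Simulation configuration for synthetic polarity cohorts
#'
#' Bundles and validates every knob of the synthetic 4D generator. The
#' generator emulates the statistical structure the polarity analysis
#' assumes: voxel time series whose tercile codes aggregate into three
#' whole-brain regimes (one with far more than a third of voxels High, one
#' with far more than a third Low, one balanced), spatially smooth voxel
#' participation with ventricle-like non-participating zones, a
#' diagnosis-linked suppression of polarized-regime occupancy, and
#' band-limited network timecourses.
#'
#' @param grid_shape 3 positive integers, voxels per axis. An ellipsoidal
#'   gray-matter-like mask is inscribed in this grid.
#' @param n_timepoints number of TRs per scan (>= 30).
#' @param tr_seconds repetition time in seconds.
#' @param n_hc,n_sz subjects per group.
#' @param regime_dwell_mean mean dwell time (TRs) of a polarized whole-brain
#'   regime; dwell times are geometric (a 3-state Markov chain on
#'   High/Low/Neutral) and the balanced regime dwells 1.5 times as long, so
#'   it is the most occupied one.
#' @param polarization_gain_hc,polarization_gain_sz amplitude (in units of
#'   the unit-variance voxel noise) of the shared regime signal for each
#'   group; the SZ gain must not exceed the HC gain when `sz_suppression`
#'   is on. Defaults are calibrated so that group occupancy differences are
#'   on the order of a few percent of scan time.
#' @param n_regions number of high-participation blobs in the participation
#'   field.
#' @param noise_sd standard deviation of the white voxel noise.
#' @param network_amplitude amplitude of the shared band-limited network
#'   component added to voxels under each network map.
#' @param sz_suppression logical; if TRUE (default) the SZ group's gain is
#'   suppressed relative to HC.
#' @param motion_confound logical; if TRUE, both groups share the HC gain
#'   but head motion (meanFD) is higher in SZ and itself suppresses the
#'   gain, creating a motion-confounded group difference for testing
#'   nuisance correction. Default FALSE (meanFD independent of group).
#' @param seed master integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(16L, 16L, 8L),
                       n_timepoints = 160L,
                       tr_seconds = 2,
                       n_hc = 4L,
                       n_sz = 4L,
                       regime_dwell_mean = 5,
                       polarization_gain_hc = 1.4,
                       polarization_gain_sz = 0.7,
                       n_regions = 4L,
                       noise_sd = 1,
                       network_amplitude = 0.4,
                       sz_suppression = TRUE,
                       motion_confound = FALSE,
                       seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            n_timepoints >= 30L, tr_seconds > 0,
            regime_dwell_mean > 0, polarization_gain_hc >= 0,
            polarization_gain_sz >= 0, n_regions >= 1L, noise_sd > 0,
            network_amplitude >= 0)
  if (sz_suppression && polarization_gain_sz > polarization_gain_hc) {
    stop("SZ suppression scenario requires polarization_gain_sz <= polarization_gain_hc")
  }
  cfg <- list(grid_shape = as.integer(grid_shape),
              n_timepoints = as.integer(n_timepoints),
              tr_seconds = tr_seconds, n_hc = as.integer(n_hc),
              n_sz = as.integer(n_sz), regime_dwell_mean = regime_dwell_mean,
              polarization_gain_hc = polarization_gain_hc,
              polarization_gain_sz = polarization_gain_sz,
              n_regions = as.integer(n_regions), noise_sd = noise_sd,
              network_amplitude = network_amplitude,
              sz_suppression = isTRUE(sz_suppression),
              motion_confound = isTRUE(motion_confound),
              seed = as.integer(seed))
  msk <- ellipsoid_mask(cfg$grid_shape)
  if (nrow(msk) < 100L) stop("masked grid too small: need >= 100 voxels, got ",
                             nrow(msk))
  class(cfg) <- "sim_config"
  cfg
}

# Coordinates (V x 3) of voxels inside the ellipsoid inscribed in the grid,
# in the canonical x-then-y-then-z order.
ellipsoid_mask <- function(dim3) {
  ctr <- (dim3 + 1) / 2
  semi <- dim3 / 2
  g <- as.matrix(expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                             z = seq_len(dim3[3])))
  r2 <- ((g[, 1] - ctr[1]) / semi[1])^2 + ((g[, 2] - ctr[2]) / semi[2])^2 +
    ((g[, 3] - ctr[3]) / semi[3])^2
  g[r2 <= 1, , drop = FALSE]
}

# Sum-of-Gaussian-blobs field over masked voxel coordinates, in [0, 1].
gauss_blob_field <- function(coords, centers, sigma) {
  f <- numeric(nrow(coords))
  for (i in seq_len(nrow(centers))) {
    d2 <- (coords[, 1] - centers[i, 1])^2 + (coords[, 2] - centers[i, 2])^2 +
      (coords[, 3] - centers[i, 3])^2
    f <- f + exp(-d2 / (2 * sigma^2))
  }
  pmin(f, 1)
}

# Geometric-dwell 3-state regime sequence over {High, Low, Neutral}.
# Polarized regimes dwell `dwell` TRs on average and exit to Neutral with
# probability 0.8 (0.2 to the opposite polarity); Neutral dwells 1.5x as
# long and exits to High or Low equally. This makes the balanced regime
# the most occupied one (~55% of TRs) with polarized episodes of a few
# TRs' duration interleaved, the banding structure the analysis targets.
simulate_regime_sequence <- function(n_timepoints, dwell) {
  states <- c("High", "Low", "Neutral")
  p_leave <- c(min(1, 1 / dwell), min(1, 1 / dwell), min(1, 1 / (1.5 * dwell)))
  s <- integer(n_timepoints)
  s[1] <- 3L
  for (t in seq_len(n_timepoints - 1L)) {
    s[t + 1L] <- if (stats::runif(1) < p_leave[s[t]]) {
      if (s[t] == 3L) sample(1:2, 1L)
      else if (stats::runif(1) < 0.8) 3L else 3L - s[t]
    } else s[t]
  }
  factor(states[s], levels = states)
}

#' Generate smooth, approximately disjoint network spatial maps
#'
#' Stands in for group-ICA resting-state network maps: each map is a smooth
#' nonnegative blob over the masked grid; blob centers are placed by
#' farthest-point sampling so the maps' high-valued voxel sets are
#' approximately disjoint.
#'
#' @param config a [sim_config()].
#' @param n_networks number of maps (>= 2).
#' @return a V x n_networks matrix with attributes `coords` and `dim3`.
#' @export
generate_network_maps <- function(config, n_networks) {
  stopifnot(inherits(config, "sim_config"), n_networks >= 2L)
  coords <- ellipsoid_mask(config$grid_shape)
  sigma <- min(config$grid_shape) / 5
  withr_seed(config$seed + 77L, {
    centers <- farthest_point_centers(coords, n_networks)
  })
  dmin <- min(stats::dist(centers))
  if (dmin < 2 * sigma) {
    stop("cannot place ", n_networks,
         " approximately disjoint network blobs on this grid")
  }
  maps <- sapply(seq_len(n_networks), function(i) {
    gauss_blob_field(coords, centers[i, , drop = FALSE], sigma)
  })
  colnames(maps) <- paste0("net", seq_len(n_networks))
  attr(maps, "coords") <- coords
  attr(maps, "dim3") <- config$grid_shape
  maps
}

farthest_point_centers <- function(coords, n) {
  centers <- coords[sample.int(nrow(coords), 1L), , drop = FALSE]
  while (nrow(centers) < n) {
    d <- sapply(seq_len(nrow(coords)), function(i) {
      min(colSums((t(centers) - coords[i, ])^2))
    })
    centers <- rbind(centers, coords[which.max(d), ])
  }
  centers
}

# Evaluate expr with a local RNG seed, restoring the RNG state afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic subject
#'
#' Builds a masked 4D scan as
#' `gain * s_v * g(t) + network component + white noise`, where `g(t)` is
#' +1 / -1 / 0 during High / Low / Neutral whole-brain regimes of a
#' geometric-dwell chain, and `s_v` in \[0,1\] is a spatially smooth
#' participation field with a few high-participation blobs and a
#' ventricle-like central zone of zero participation. The group label
#' determines the gain (with per-SZ-subject variation that the simulated
#' symptom scores track).
#'
#' @param config a [sim_config()].
#' @param group `"HC"` or `"SZ"`.
#' @param subject_seed integer seed for this subject.
#' @return a list with `series` ([masked_series()]), `true_regimes`
#'   (length-T factor), `true_participation` (V-vector in \[0,1\]),
#'   `gain` (realized gain) and `metadata` (one-row data.frame).
#' @export
generate_subject <- function(config, group, subject_seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!group %in% c("HC", "SZ")) stop("group must be 'HC' or 'SZ', got '",
                                      group, "'")
  coords <- ellipsoid_mask(config$grid_shape)
  V <- nrow(coords); T <- config$n_timepoints
  nets <- generate_network_maps(config, max(2L, min(4L, config$n_regions)))
  withr_seed(subject_seed, {
    # participation field: blobs minus a central ventricle-like zone
    centers <- farthest_point_centers(coords, config$n_regions)
    s_v <- gauss_blob_field(coords, centers, min(config$grid_shape) / 4)
    ctr <- (config$grid_shape + 1) / 2
    vent <- ((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2 +
               (coords[, 3] - ctr[3])^2) <= (min(config$grid_shape) / 5)^2
    s_v[vent] <- 0
    regimes <- simulate_regime_sequence(T, config$regime_dwell_mean)
    g_t <- c(High = 1, Low = -1, Neutral = 0)[as.character(regimes)]

    meta <- simulate_metadata_row(config, group)
    gain <- meta$.gain

    tcs <- matrix(stats::rnorm(ncol(nets) * T), ncol(nets), T)
    tcs <- bandpass_timecourses(tcs, tr_seconds = config$tr_seconds)
    net_comp <- config$network_amplitude * (nets %*% tcs)

    x <- gain * outer(s_v, g_t) + net_comp +
      matrix(stats::rnorm(V * T, sd = config$noise_sd), V, T)
  })
  meta$.gain <- NULL
  list(series = masked_series(x, coords, config$grid_shape,
                              config$tr_seconds),
       true_regimes = regimes,
       true_participation = s_v,
       gain = gain,
       metadata = meta)
}

# One metadata row; must be called inside the subject's seeded block so that
# a subject is fully reproducible from (config, group, subject_seed).
simulate_metadata_row <- function(config, group) {
  age <- round(stats::runif(1, 18, 60))
  gender <- sample(c("M", "F"), 1L)
  if (config$motion_confound) {
    # motion differs by group and suppresses the gain; base gains are equal,
    # so any group difference is carried entirely by motion
    mean_fd <- stats::rlnorm(1, log(if (group == "SZ") 0.25 else 0.12), 0.3)
    gain <- config$polarization_gain_hc * exp(-3 * max(0, mean_fd - 0.1))
  } else {
    mean_fd <- stats::rlnorm(1, log(0.15), 0.4)
    gain <- if (group == "HC") config$polarization_gain_hc else {
      if (config$sz_suppression) {
        config$polarization_gain_sz * stats::runif(1, 0.6, 1.4)
      } else config$polarization_gain_hc
    }
  }
  if (group == "SZ") {
    supp <- (config$polarization_gain_hc - gain) /
      max(config$polarization_gain_hc, 1e-12)
    sympt_pos <- round(pmin(49, pmax(7, 8 + 25 * supp + stats::rnorm(1, 0, 1.5))))
    sympt_neg <- round(pmin(49, pmax(7, 10 + 8 * supp + stats::rnorm(1, 0, 3))))
    sympt_gen <- round(pmin(112, pmax(16, 20 + 10 * supp + stats::rnorm(1, 0, 5))))
  } else {
    sympt_pos <- sympt_neg <- sympt_gen <- NA_real_
  }
  data.frame(group = group, age = age, gender = gender, mean_fd = mean_fd,
             sympt_pos = sympt_pos, sympt_neg = sympt_neg,
             sympt_gen = sympt_gen, .gain = gain,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Per-subject seeds are derived deterministically from the config seed, so
#' two cohorts from the same config are identical. Symptom columns are NA
#' for HC rows; for SZ rows the positive-symptom score is positively
#' correlated with that subject's realized gain suppression.
#'
#' @param config a [sim_config()].
#' @return list with `subjects` (list from [generate_subject()]) and
#'   `cohort` (data.frame with columns subject_id, group, age, gender,
#'   mean_fd, sympt_pos, sympt_neg, sympt_gen).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_hc + config$n_sz
  if (n < 2L) stop("need at least 2 subjects")
  groups <- rep(c("HC", "SZ"), c(config$n_hc, config$n_sz))
  seeds <- withr_seed(config$seed, sample.int(.Machine$integer.max - 1L, n))
  subjects <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- generate_subject(config, groups[i], seeds[i])
    rows[[i]] <- cbind(data.frame(subject_id = sprintf("sub%03d", i),
                                  stringsAsFactors = FALSE),
                       subjects[[i]]$metadata)
  }
  list(subjects = subjects, cohort = do.call(rbind, rows))
}

#' Row-stochastic transition-matrix fixtures
#'
#' Builds k x k transition matrices with known itinerary structure for
#' testing the most-probable-itinerary extraction:
#' \describe{
#'   \item{cycle}{embeds a length-`orbit_length` circuit over the first
#'     states: every state's most probable distinct successor leads into and
#'     around the circuit.}
#'   \item{oscillation}{embeds a 2-state alternation (states 1 and 2) that
#'     all other states feed into.}
#'   \item{random}{Dirichlet-like random rows.}
#' }
#' All rows sum to 1; a moderate self-transition mass is included since
#' itineraries are over distinct-state transitions.
#'
#' @param n_states number of states (>= 2).
#' @param scenario `"cycle"`, `"oscillation"` or `"random"`.
#' @param seed integer seed.
#' @param orbit_length circuit length for the cycle scenario (default
#'   `min(9, n_states)`).
#' @return an n_states x n_states row-stochastic matrix.
#' @export
generate_transition_fixture <- function(n_states,
                                        scenario = c("cycle", "oscillation", "random"),
                                        seed = 1L,
                                        orbit_length = min(9L, n_states)) {
  scenario <- match.arg(scenario)
  stopifnot(n_states >= 2L, orbit_length >= 2L, orbit_length <= n_states)
  k <- n_states
  withr_seed(seed, {
    P <- matrix(stats::runif(k * k, 0.01, 0.05), k, k)
    diag(P) <- stats::runif(k, 0.2, 0.4)
    if (scenario == "cycle") {
      orbit <- seq_len(orbit_length)
      for (i in orbit) {
        nxt <- if (i == orbit_length) 1L else i + 1L
        P[i, nxt] <- 0.5
      }
      if (orbit_length < k) {
        for (i in seq.int(orbit_length + 1L, k)) P[i, 1L] <- 0.5
      }
    } else if (scenario == "oscillation") {
      P[1L, 2L] <- 0.5; P[2L, 1L] <- 0.5
      if (k > 2L) for (i in 3:k) P[i, 1L] <- 0.5
    }
    P / rowSums(P)
  })
}
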