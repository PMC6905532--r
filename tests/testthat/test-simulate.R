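test_that("subject generation is seeded-deterministic and validates the group", {
  cfg <- sim_config(grid_shape = c(10L, 10L, 5L), n_timepoints = 40L, seed = 2L)
  a <- generate_subject(cfg, "SZ", 99L)
  b <- generate_subject(cfg, "SZ", 99L)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$true_regimes, b$true_regimes)
  expect_identical(a$metadata, b$metadata)
  expect_error(generate_subject(cfg, "XX", 1L), "group")

  expect_equal(length(a$true_regimes), 40L)
  expect_true(all(a$true_participation >= 0 & a$true_participation <= 1))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_timepoints = 10L))
  expect_error(sim_config(polarization_gain_hc = 0.5,
                          polarization_gain_sz = 1.0), "suppression")
  expect_error(sim_config(grid_shape = c(4L, 4L, 3L)), "100 voxels")
})

test_that("zero gain leaves proportions hovering near a third", {
  cfg <- sim_config(grid_shape = c(10L, 10L, 5L), n_timepoints = 120L,
                    polarization_gain_hc = 0, polarization_gain_sz = 0,
                    network_amplitude = 0, seed = 6L)
  sub <- generate_subject(cfg, "HC", 11L)
  pr <- polarity_proportions(discretize_ial(zscore_voxels(sub$series)))
  expect_equal(mean(pr$h), 1 / 3, tolerance = 0.02)
  expect_equal(mean(pr$l), 1 / 3, tolerance = 0.02)
  expect_lt(max(pr$h), 0.42)                # no polarized excursions
})

test_that("strong gain with long dwells produces frequent high-h epochs", {
  # threshold calibrated once on the generator itself and frozen
  cfg <- sim_config(grid_shape = c(12L, 12L, 6L), n_timepoints = 160L,
                    polarization_gain_hc = 3, regime_dwell_mean = 10,
                    noise_sd = 0.8, seed = 13L)
  frac <- sapply(1:3, function(i) {
    sub <- generate_subject(cfg, "HC", 100L + i)
    pr <- polarity_proportions(discretize_ial(zscore_voxels(sub$series)))
    mean(pr$h > 0.40)
  })
  expect_gt(mean(frac), 0.2)
})

test_that("polarization fraction rises monotonically with gain", {
  frac_polar <- function(gain, seed) {
    cfg <- sim_config(grid_shape = c(10L, 10L, 5L), n_timepoints = 100L,
                      polarization_gain_hc = max(gain, 0.01),
                      polarization_gain_sz = 0, seed = seed)
    sub <- generate_subject(cfg, if (gain == 0) "SZ" else "HC", seed * 3L + 1L)
    pr <- polarity_proportions(discretize_ial(zscore_voxels(sub$series)))
    mean(pmax(pr$h, pr$l) > 0.40)
  }
  gains <- c(0, 0.8, 1.6, 2.6)
  means <- sapply(gains, function(g) mean(sapply(1:20, frac_polar, gain = g)))
  expect_true(all(diff(means) > 0))
})

test_that("cohorts have complete metadata and symptom scores only for patients", {
  cfg <- sim_config(grid_shape = c(10L, 10L, 5L), n_timepoints = 40L,
                    n_hc = 2L, n_sz = 2L, seed = 21L)
  coh <- generate_cohort(cfg)
  tab <- coh$cohort
  expect_equal(nrow(tab), 4L)
  expect_identical(tab$group, c("HC", "HC", "SZ", "SZ"))
  expect_true(all(is.na(tab[tab$group == "HC", c("sympt_pos", "sympt_neg", "sympt_gen")])))
  expect_true(all(!is.na(tab[tab$group == "SZ", c("sympt_pos", "sympt_neg", "sympt_gen")])))
  expect_true(all(tab$mean_fd > 0))

  coh2 <- generate_cohort(cfg)
  expect_identical(tab, coh2$cohort)
  expect_identical(coh$subjects[[3]]$series$data, coh2$subjects[[3]]$series$data)
})

test_that("positive symptoms track each patient's gain suppression", {
  cfg <- sim_config(grid_shape = c(10L, 10L, 5L), n_timepoints = 40L,
                    n_hc = 0L, n_sz = 30L, seed = 31L)
  coh <- generate_cohort(cfg)
  gains <- sapply(coh$subjects, `[[`, "gain")
  suppression <- cfg$polarization_gain_hc - gains
  expect_gt(cor(suppression, coh$cohort$sympt_pos), 0.5)
})

test_that("network maps are smooth, disjoint at the top and repeatable", {
  cfg <- sim_config(grid_shape = c(10L, 10L, 5L), n_timepoints = 40L, seed = 3L)
  maps <- generate_network_maps(cfg, 2L)
  expect_true(all(is.finite(maps)))
  expect_true(all(colSums(maps) > 0))
  top_decile <- apply(maps, 2L, function(m) which(m >= quantile(m, 0.9)))
  expect_length(intersect(top_decile[[1]], top_decile[[2]]), 0L)
  expect_identical(maps, generate_network_maps(cfg, 2L))
  expect_error(generate_network_maps(cfg, 60L), "disjoint")
})

test_that("transition fixtures are row-stochastic with planted structure", {
  for (sc in c("cycle", "oscillation", "random")) {
    P <- generate_transition_fixture(13L, sc, seed = 8L)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0))
  }
  P9 <- generate_transition_fixture(13L, "cycle", seed = 8L, orbit_length = 9L)
  expect_equal(most_probable_itinerary(P9, 12L)$orbit_length, 9L)
  P2 <- generate_transition_fixture(6L, "oscillation", seed = 8L)
  expect_equal(most_probable_itinerary(P2, 5L)$orbit_length, 2L)
})

test_that("downstream regime clustering recovers the planted structure", {
  sc <- small_cohort()
  cen <- sc$dpr$centroids
  third <- rep(1 / 3, 3)
  expect_gt(cen["Polarized-High", "h"], 0.40)
  expect_lt(cen["Polarized-High", "l"], 0.30)
  expect_gt(cen["Polarized-Low", "l"], 0.40)
  expect_lt(cen["Polarized-Low", "h"], 0.30)
  expect_lt(max(abs(cen["Non-Polarized", ] - third)), 0.05)

  # diagnosis-linked suppression: HC occupy polarized regimes more
  occ <- occupancy_rates(sc$dpr)
  pol <- rowSums(occ[, polarized_states(sc$dpr)])
  grp <- sc$cohort$group
  expect_gt(mean(pol[grp == "HC"]), mean(pol[grp == "SZ"]))
})
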