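#' Pipeline configuration
#'
#' Resolves and validates all stage parameters of the end-to-end polarity
#' pipeline, with defaults matching the analysis protocol: 3 polarity
#' regimes, 2 participation-map clusters, 13 co-polarization patterns, 5
#' connectivity states, alpha = 0.001 with 47 independent spatial units for
#' the strong-polarization test, a 22-TR tapered window, a [0.05, 0.15] Hz
#' band and a 1.25 network-map z threshold. Unknown keys are rejected.
#'
#' @param sim a [sim_config()] describing the cohort to simulate.
#' @param ... overrides for the parameters listed above (`k_dpr`, `k_ppm`,
#'   `k_copp`, `k_dfnc`, `alpha`, `n_independent_units`, `window_length`,
#'   `band_hz`, `map_z_threshold`, `replicates`, `seed`, plus stage toggles
#'   `run_copp`, `run_itinerary`, `run_dfnc`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), ...) {
  cfg <- list(sim = sim, k_dpr = 3L, k_ppm = 2L, k_copp = 13L, k_dfnc = 5L,
              alpha = 0.001, n_independent_units = 47L, window_length = 22L,
              band_hz = c(0.05, 0.15), map_z_threshold = 1.25,
              replicates = 10L, seed = 1L,
              run_copp = TRUE, run_itinerary = TRUE, run_dfnc = TRUE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown pipeline config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(inherits(cfg$sim, "sim_config"), cfg$alpha > 0, cfg$alpha < 1,
            cfg$window_length >= 3L, length(cfg$band_hz) == 2L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full polarity pipeline on a simulated cohort
#'
#' Executes simulate -> z-score/discretize -> polarity regimes ->
#' participation maps -> co-polarization patterns -> itineraries ->
#' sliding-window connectivity -> group statistics, optionally writing
#' per-stage artifacts and a machine-readable summary to `out_dir`.
#' Runs are idempotent given the seed embedded in the config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, stage artifacts
#'   (cohort CSV, occupancy CSV, state model JSON, effect tables, resolved
#'   config and summary JSON) are written there.
#' @return a list of stage results plus a `summary` list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!config$run_copp && config$run_itinerary) {
    warning("itinerary stage requires the CoPP stage; skipping itineraries")
    config$run_itinerary <- FALSE
  }
  res <- list(config = config)

  cohort_sim <- generate_cohort(config$sim)
  cohort <- cohort_sim$cohort
  subjects <- cohort_sim$subjects

  ials <- lapply(subjects, function(s) discretize_ial(zscore_voxels(s$series)))
  props <- lapply(ials, polarity_proportions)
  names(ials) <- names(props) <- cohort$subject_id

  dpr <- fit_dpr(props, k = config$k_dpr, seed = config$seed,
                 replicates = config$replicates)
  occ <- occupancy_rates(dpr)
  pol_occ <- rowSums(occ[, polarized_states(dpr), drop = FALSE])

  ppms <- mapply(function(ial, id) compute_ppm(ial, dpr$labels[[id]],
                                               subject_id = id),
                 ials, cohort$subject_id, SIMPLIFY = FALSE)
  ppm_clusters <- cluster_ppms(ppms, k = config$k_ppm, seed = config$seed,
                               replicates = config$replicates)

  covs <- data.frame(age = cohort$age, gender = factor(cohort$gender),
                     mean_fd = cohort$mean_fd)
  group_effect <- nuisance_regression(pol_occ, cohort$group, covs,
                                      response_id = "polarized_occupancy")

  res <- c(res, list(cohort = cohort, dpr = dpr, occupancy = occ,
                     polarized_occupancy = pol_occ, ppms = ppms,
                     ppm_clusters = ppm_clusters,
                     group_effect = group_effect))

  if (config$run_copp) {
    copp <- fit_copps(ials, k = min(config$k_copp, length(ials) *
                                      config$sim$n_timepoints %/% 20L),
                      seed = config$seed, replicates = config$replicates)
    copp_class <- classify_copps(copp, alpha = config$alpha,
                                 n_independent_units = config$n_independent_units)
    res$copp <- copp
    res$copp_class <- copp_class
    if (config$run_itinerary) {
      by_group <- split(copp$labels, cohort$group)
      trans <- lapply(names(by_group), function(g) {
        estimate_transitions(by_group[[g]], k = copp$k, group = g)
      })
      names(trans) <- names(by_group)
      pol_states <- which(copp_class != "neutral")
      sources <- if (length(pol_states)) pol_states else 1L
      res$transitions <- trans
      if (length(trans) == 2L) {
        res$itineraries <- compare_group_itineraries(trans[[1]], trans[[2]],
                                                     sources, copp_class)
      }
    }
  }

  if (config$run_dfnc) {
    nets <- generate_network_maps(config$sim, 4L)
    win_list <- lapply(subjects, function(s) {
      tc <- t(nets) %*% s$series$data / colSums(nets)
      tc <- bandpass_timecourses(tc, config$band_hz[1], config$band_hz[2],
                                 tr_seconds = config$sim$tr_seconds)
      sliding_window_fnc(tc, config$window_length)
    })
    names(win_list) <- cohort$subject_id
    dfnc <- fit_dfnc_states(win_list, k = min(config$k_dfnc,
                                              length(win_list) * 10L),
                            seed = config$seed,
                            replicates = config$replicates)
    coupling <- dpr_within_dfnc_test(dpr$labels, dfnc$labels, cohort$group,
                                     window_length = config$window_length)
    fnc <- do.call(rbind, lapply(subjects, function(s) {
      tc <- t(nets) %*% s$series$data / colSums(nets)
      tc <- bandpass_timecourses(tc, config$band_hz[1], config$band_hz[2],
                                 tr_seconds = config$sim$tr_seconds)
      static_fnc(tc)
    }))
    mediation <- fnc_mediation_comparison(fnc, cohort, pol_occ)
    res$dfnc <- dfnc
    res$dpr_dfnc_coupling <- coupling
    res$fnc <- fnc
    res$mediation <- mediation
  }

  res$summary <- list(
    n_subjects = nrow(cohort),
    n_voxels = nrow(subjects[[1]]$series$data),
    n_timepoints = config$sim$n_timepoints,
    dpr_centroids = res$dpr$centroids,
    mean_polarized_occupancy = tapply(pol_occ, cohort$group, mean),
    group_beta = group_effect$beta,
    group_p = group_effect$p,
    n_strong_copps = if (!is.null(res$copp_class))
      sum(res$copp_class != "neutral") else NA,
    seed = config$seed)

  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  occ <- as.data.frame(res$occupancy)
  names(occ) <- paste0("state", seq_len(ncol(occ)))
  occ$subject_id <- res$cohort$subject_id
  utils::write.csv(occ, file.path(out_dir, "dpr_occupancy.csv"),
                   row.names = FALSE)
  write_state_model(res$dpr, file.path(out_dir, "dpr_model.json"))
  utils::write.csv(res$group_effect, file.path(out_dir, "group_effect.csv"),
                   row.names = FALSE)
  if (!is.null(res$dpr_dfnc_coupling)) {
    utils::write.csv(res$dpr_dfnc_coupling,
                     file.path(out_dir, "dpr_dfnc_coupling.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$itineraries)) {
    utils::write.csv(res$itineraries, file.path(out_dir, "itineraries.csv"),
                     row.names = FALSE)
  }
  cfg <- res$config
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
                       force = TRUE)
  invisible(out_dir)
}
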