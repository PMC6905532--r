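# Shared study configuration for the analysis scripts. Every script
# re-derives the cohort deterministically from this config, so the stages
# can be run independently and in any order.

suppressPackageStartupMessages(library(brainpolarity))

STUDY_SEED <- 1234L

study_config <- function() {
  sim_config(grid_shape = c(16L, 16L, 8L), n_timepoints = 160L,
             n_hc = 8L, n_sz = 8L, seed = STUDY_SEED)
}

results_dir <- function() {
  d <- file.path("results")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# Cohort plus the polarity-coded representations used by several stages.
build_study <- function() {
  cfg <- study_config()
  coh <- generate_cohort(cfg)
  ials <- lapply(coh$subjects, function(s) discretize_ial(zscore_voxels(s$series)))
  names(ials) <- coh$cohort$subject_id
  props <- lapply(ials, polarity_proportions)
  dpr <- fit_dpr(props, k = 3L, seed = STUDY_SEED, replicates = 20L)
  list(cfg = cfg, cohort = coh$cohort, subjects = coh$subjects,
       ials = ials, props = props, dpr = dpr)
}

nuisance_covs <- function(cohort) {
  data.frame(age = cohort$age, gender = factor(cohort$gender),
             mean_fd = cohort$mean_fd)
}
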