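#' Fit brainwide co-polarization patterns (CoPPs)
#'
#' Clusters the polarity-coded whole-brain volumes (V-vectors over
#' \{-1, 0, +1\}, one per subject-TR) with best-of-replicates k-means.
#' Centroid entries are per-voxel means in \[-1, 1\]; each centroid's grand
#' mean (mu_CoPP) summarizes how pervasively polarized the pattern is, and
#' population occupancy rates give the effective sample size used by the
#' conservative significance test.
#'
#' @param ial_list list of per-subject `ial_matrix` objects (or V x T level
#'   matrices); samples are the transposed columns, stacked over subjects.
#' @param k number of patterns (default 13).
#' @param seed,replicates as in [fit_dpr()].
#' @return a `copp_model` (a `state_model` with extra fields):
#'   `centroid_means` (mu per centroid), `occupancy_rates_population`
#'   (r_i, summing to 1), `effective_n` (n_i = n_subjects * r_i) and
#'   `n_subjects`.
#' @export
fit_copps <- function(ial_list, k = 13L, seed = 1L, replicates = 20L) {
  mats <- lapply(ial_list, function(m) {
    lev <- if (inherits(m, "ial_matrix")) m$levels else m
    if (!all(lev %in% c(-1L, 0L, 1L))) stop("IAL entries must lie in {-1, 0, +1}")
    t(lev)
  })
  x <- do.call(rbind, mats)
  fit <- kmeans_states(x, k, seed, replicates)
  lens <- vapply(mats, nrow, integer(1))
  idx <- split(seq_along(fit$cluster), rep(seq_along(mats), lens))
  labels <- lapply(idx, function(i) fit$cluster[i])
  names(labels) <- names(ial_list)
  model <- new_state_model(fit$centers, labels, k, seed)
  n_subjects <- length(labels)
  r_i <- tabulate(fit$cluster, nbins = k) / length(fit$cluster)
  model$centroid_means <- rowMeans(fit$centers)
  model$occupancy_rates_population <- r_i
  model$effective_n <- n_subjects * r_i
  model$n_subjects <- n_subjects
  class(model) <- c("copp_model", class(model))
  model
}

#' Magnitude threshold for a strongly polarized CoPP
#'
#' Conservative null for the grand mean mu of a CoPP centroid: treating the
#' IAL values as iid uniform over \{-1, 0, +1\} (mean 0, variance 2/3) the
#' naive CLT null for mu has vanishing variance at realistic sample sizes
#' (scale factors above 1e7), so magnitudes as small as 1e-5 would land in
#' the extreme alpha = 0.001 tails. Two reductions make the null
#' conservative: all timepoints of a subject are treated as one dependent
#' sample, so cluster i contributes n_i = n_subjects * r_i effective
#' samples; and space is reduced to `n_independent_units` independent units
#' (47 by default, the number of meaningful group-ICA networks). The null
#' is then N(0, 1 / (units * n_i)) and the returned cut is its upper-alpha
#' (or alpha/2) quantile.
#'
#' @param n_i effective sample count for the cluster (> 0).
#' @param n_independent_units independent spatial units (default 47).
#' @param alpha tail mass (default 0.001).
#' @param tail `"each"` (default; alpha mass in each tail) or `"total"`
#'   (alpha split across both tails).
#' @return the positive magnitude cut on |mu|.
#' @export
polarization_threshold <- function(n_i, n_independent_units = 47L,
                                   alpha = 0.001, tail = c("each", "total")) {
  tail <- match.arg(tail)
  if (any(n_i <= 0)) stop("effective sample count n_i must be positive")
  p <- if (tail == "each") 1 - alpha else 1 - alpha / 2
  stats::qnorm(p) * sqrt(1 / (n_independent_units * n_i))
}

#' Classify CoPP centroids by polarization
#'
#' Centroid i is `positive` if mu_i exceeds its [polarization_threshold()],
#' `negative` if mu_i falls below the negated threshold, and `neutral`
#' otherwise. The sign of mu determines the valency.
#'
#' @param model a `copp_model` from [fit_copps()].
#' @param alpha,n_independent_units,tail as in [polarization_threshold()].
#' @return factor of length k with levels `negative`, `neutral`, `positive`.
#' @export
classify_copps <- function(model, alpha = 0.001, n_independent_units = 47L,
                           tail = "each") {
  stopifnot(inherits(model, "copp_model"))
  thr <- polarization_threshold(model$effective_n, n_independent_units,
                                alpha, tail)
  mu <- model$centroid_means
  cls <- ifelse(mu > thr, "positive", ifelse(mu < -thr, "negative", "neutral"))
  factor(cls, levels = c("negative", "neutral", "positive"))
}
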