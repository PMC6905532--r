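#' Seeded best-of-replicates k-means
#'
#' Thin wrapper around [stats::kmeans()] providing the clustering engine
#' shared by the polarity-regime (k=3), participation-map (k=2),
#' co-polarization (k=13) and connectivity-state (k=5) stages: a fixed seed,
#' a configurable number of random restarts keeping the lowest
#' within-cluster sum of squares, and re-seeding of any replicate that
#' produces an empty cluster.
#'
#' @param x numeric sample matrix (rows are observations).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param replicates random restarts (best solution kept).
#' @param iter_max maximum iterations per restart.
#' @return the best `stats::kmeans` fit.
#' @keywords internal
kmeans_states <- function(x, k, seed = 1L, replicates = 50L,
                          iter_max = 3000L) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("need at least k = ", k, " samples, got ", nrow(x))
  if (nrow(unique(x)) < k) stop("degenerate data: fewer than k distinct samples")
  best <- NULL
  for (r in seq_len(replicates)) {
    fit <- NULL
    for (attempt in 0:5) {
      fit <- withr_seed(seed + r + attempt * 100003L, {
        tryCatch(suppressWarnings(
          stats::kmeans(x, centers = k, iter.max = iter_max, nstart = 1L)
        ), error = function(e) NULL)
      })
      if (!is.null(fit) && all(fit$size > 0)) break
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all replicates")
  best
}

new_state_model <- function(centroids, labels, k, seed,
                            inertia_curve = NULL) {
  occ <- t(vapply(labels, function(lab) {
    tabulate(lab, nbins = k) / length(lab)
  }, numeric(k)))
  structure(list(centroids = centroids, labels = labels, occupancy = occ,
                 k = as.integer(k), seed = as.integer(seed),
                 inertia_curve = inertia_curve),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state_model: k = %d, %d subjects, %d features\n",
              x$k, length(x$labels), ncol(x$centroids)))
  invisible(x)
}

#' Fit dynamic polarity regimes (dPRs)
#'
#' Pools the per-TR (h, l, n) proportion 3-vectors across all subjects and
#' clusters them with best-of-replicates k-means (Euclidean distance).
#' With the default k = 3 the clusters are relabeled canonically:
#' state 1 is Polarized-High (largest centroid h component), state 2 is
#' Polarized-Low (largest l component among the rest), and the remainder is
#' Non-Polarized; ties go to the lowest original cluster index. This makes
#' labels comparable across runs regardless of k-means initialization.
#'
#' @param props_list list of per-subject proportion data.frames from
#'   [polarity_proportions()].
#' @param k number of regimes (default 3).
#' @param seed integer seed.
#' @param replicates k-means restarts (default 50).
#' @return a `state_model` with fields `centroids` (k x 3, columns h, l, n),
#'   `labels` (per-subject integer sequences), `occupancy` (subjects x k,
#'   rows summing to 1), `k`, `seed`. With k = 3 the centroid rows are named
#'   `Polarized-High`, `Polarized-Low`, `Non-Polarized`.
#' @export
fit_dpr <- function(props_list, k = 3L, seed = 1L, replicates = 50L) {
  stopifnot(is.list(props_list), length(props_list) >= 1L)
  mats <- lapply(props_list, function(p) as.matrix(p[, c("h", "l", "n")]))
  x <- do.call(rbind, mats)
  fit <- kmeans_states(x, k, seed, replicates)
  perm <- canonical_regime_order(fit$centers)
  centroids <- fit$centers[perm, , drop = FALSE]
  relab <- order(perm)                     # old label -> new label
  lens <- vapply(mats, nrow, integer(1))
  idx <- split(seq_along(fit$cluster), rep(seq_along(mats), lens))
  labels <- lapply(idx, function(i) relab[fit$cluster[i]])
  names(labels) <- names(props_list)
  if (k == 3L) {
    rownames(centroids) <- c("Polarized-High", "Polarized-Low", "Non-Polarized")
  }
  new_state_model(centroids, labels, k, seed)
}

# Canonical order: argmax-h first, argmax-l (among the rest) second, the
# remainder in original index order. Ties broken by lowest index
# (which.max's behavior).
canonical_regime_order <- function(centers) {
  hi <- which.max(centers[, 1])
  rest <- setdiff(seq_len(nrow(centers)), hi)
  lo <- rest[which.max(centers[rest, 2])]
  c(hi, lo, setdiff(rest, lo))
}

#' Indices of the polarized regimes in a dPR model
#'
#' @param model a k = 3 `state_model` from [fit_dpr()].
#' @return integer vector `c(1, 2)` (Polarized-High, Polarized-Low).
#' @export
polarized_states <- function(model) {
  stopifnot(inherits(model, "state_model"))
  c(1L, 2L)
}

#' Per-subject regime occupancy rates
#'
#' Row s, column j is the fraction of subject s's TRs assigned to state j;
#' rows sum to 1.
#'
#' @param model a fitted `state_model`.
#' @return subjects x k occupancy matrix.
#' @export
occupancy_rates <- function(model) {
  stopifnot(inherits(model, "state_model"))
  model$occupancy
}

#' Within-cluster inertia over a range of k (elbow curve)
#'
#' @param samples observation matrix.
#' @param k_range integer vector of cluster counts.
#' @param seed,replicates as in [fit_dpr()].
#' @return data.frame with columns `k` and `inertia` (total within-cluster
#'   sum of squares, nonincreasing in k given sufficient replicates).
#' @export
elbow_curve <- function(samples, k_range, seed = 1L, replicates = 20L) {
  stopifnot(length(k_range) >= 1L)
  samples <- as.matrix(samples)
  inertia <- vapply(k_range, function(k) {
    if (k >= nrow(unique(samples))) return(0)
    kmeans_states(samples, k, seed, replicates)$tot.withinss
  }, numeric(1))
  data.frame(k = as.integer(k_range), inertia = inertia)
}
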