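#' Subject-level polarity participation map (PPM)
#'
#' For each voxel, the rate at which it matches the dominant level of the
#' whole-brain polarized regime the subject occupies:
#' `PPM(v) = (#\{t: regime High, IAL_v(t) = +1\} +
#'            #\{t: regime Low, IAL_v(t) = -1\}) / #\{t: regime polarized\}`.
#' The combined-count denominator guarantees values in \[0, 1\]. Neutral
#' (non-polarized) TRs never enter the map.
#'
#' @param ial an `ial_matrix` (or V x T level matrix).
#' @param dpr_labels length-T integer regime labels aligned with the IAL
#'   time axis (1 = Polarized-High, 2 = Polarized-Low, as produced by
#'   [fit_dpr()]).
#' @param high_state,low_state the label values marking the two polarized
#'   regimes.
#' @param per_state if TRUE, use the alternative literal reading that sums
#'   the two within-state proportions (range \[0, 2\]); default FALSE.
#' @param subject_id optional identifier carried in the result.
#' @return a `ppm` object: list with `values` (V-vector), `n_polarized_trs`,
#'   `valid` (FALSE when the subject has no polarized TRs) and `subject_id`.
#' @export
compute_ppm <- function(ial, dpr_labels, high_state = 1L, low_state = 2L,
                        per_state = FALSE, subject_id = NA_character_) {
  lev <- if (inherits(ial, "ial_matrix")) ial$levels else ial
  if (length(dpr_labels) != ncol(lev)) {
    stop("dpr_labels length (", length(dpr_labels),
         ") does not match IAL time axis (", ncol(lev), ")")
  }
  hi <- which(dpr_labels == high_state)
  lo <- which(dpr_labels == low_state)
  n_pol <- length(hi) + length(lo)
  if (n_pol == 0L) {
    warning("subject has no polarized TRs; PPM invalid")
    return(structure(list(values = rep(NA_real_, nrow(lev)),
                          n_polarized_trs = 0L, valid = FALSE,
                          subject_id = subject_id), class = "ppm"))
  }
  hits_hi <- if (length(hi)) rowSums(lev[, hi, drop = FALSE] == 1L) else 0
  hits_lo <- if (length(lo)) rowSums(lev[, lo, drop = FALSE] == -1L) else 0
  vals <- if (per_state) {
    p_hi <- if (length(hi)) hits_hi / length(hi) else 0
    p_lo <- if (length(lo)) hits_lo / length(lo) else 0
    p_hi + p_lo
  } else {
    (hits_hi + hits_lo) / n_pol
  }
  structure(list(values = vals, n_polarized_trs = n_pol, valid = TRUE,
                 subject_id = subject_id), class = "ppm")
}

ppm_matrix <- function(maps) {
  maps <- maps[vapply(maps, function(m) isTRUE(m$valid), logical(1))]
  if (!length(maps)) stop("no valid participation maps")
  do.call(rbind, lapply(maps, `[[`, "values"))
}

#' Cluster subject participation maps
#'
#' K-means over the subjects' V-dimensional PPM vectors (default k = 2).
#' Clusters are ordered so that cluster 1 has the higher mean participation,
#' making "the high-participation cluster" a stable reference across runs.
#'
#' @param maps list of [compute_ppm()] results (invalid maps are dropped).
#' @param k number of clusters (default 2).
#' @param seed,replicates as in [fit_dpr()].
#' @return a `state_model` whose `labels` holds one label per subject (each
#'   a length-1 sequence) and whose `centroids` are the k mean maps.
#' @export
cluster_ppms <- function(maps, k = 2L, seed = 1L, replicates = 50L) {
  x <- ppm_matrix(maps)
  if (nrow(x) < k) stop("fewer valid maps (", nrow(x), ") than clusters (", k, ")")
  fit <- kmeans_states(x, k, seed, replicates)
  ord <- order(rowMeans(fit$centers), decreasing = TRUE)
  relab <- match(seq_len(k), ord)
  labels <- lapply(relab[fit$cluster], identity)
  new_state_model(fit$centers[ord, , drop = FALSE], labels, k, seed)
}

#' Network-level polarity participation
#'
#' Projects a subject's participation map onto network spatial maps: each
#' network map is z-scored over the masked voxels and thresholded (default
#' z >= 1.25, retaining roughly the top decile under Gaussianity); the
#' subject's PPM is likewise z-scored over voxels; the network value is the
#' mean z-scored participation over that network's supra-threshold voxels.
#' Values can be negative, meaning the network's voxels participate in
#' whole-brain polarization at a below-average rate.
#'
#' @param ppm a [compute_ppm()] result.
#' @param network_maps V x n matrix of network spatial maps (same voxel
#'   order as the PPM).
#' @param map_z_threshold threshold on the z-scored network maps.
#' @return named numeric vector, one value per network; NA (with a warning)
#'   for networks with no supra-threshold voxels.
#' @export
network_participation <- function(ppm, network_maps, map_z_threshold = 1.25) {
  vals <- if (inherits(ppm, "ppm")) ppm$values else ppm
  nm <- as.matrix(network_maps)
  if (length(vals) != nrow(nm)) stop("PPM and network maps differ in voxel count")
  if (stats::sd(vals) == 0) stop("constant participation map cannot be z-scored")
  pz <- as.vector(scale(vals))
  out <- vapply(seq_len(ncol(nm)), function(j) {
    m <- nm[, j]
    if (stats::sd(m) == 0) return(NA_real_)
    sel <- as.vector(scale(m)) >= map_z_threshold
    if (!any(sel)) return(NA_real_)
    mean(pz[sel])
  }, numeric(1))
  names(out) <- colnames(nm)
  if (anyNA(out)) {
    warning("network(s) with no supra-threshold voxels: ",
            paste(which(is.na(out)), collapse = ", "))
  }
  out
}

#' Voxelwise group-difference statistics with FDR control
#'
#' Per-voxel tests over subjects' participation maps with
#' Benjamini-Hochberg control at `q` across voxels. Two contrasts:
#' \describe{
#'   \item{`mean`}{one-sample t-test of each voxel's values against the
#'     grand mean participation rate over all voxels and subjects.}
#'   \item{`group`}{per-voxel linear model `value ~ group + covariates`;
#'     the reported statistic is the t value of the group term.}
#' }
#'
#' @param maps list of [compute_ppm()] results or a subjects x V matrix.
#' @param groups factor/character of length n_subjects (required for the
#'   `group` contrast).
#' @param covariates optional data.frame of per-subject nuisance covariates.
#' @param contrast `"mean"` or `"group"`.
#' @param q FDR level (default 0.05).
#' @return data.frame with columns `voxel`, `t`, `p`, `p_fdr`, `significant`.
#' @export
voxelwise_group_difference <- function(maps, groups = NULL, covariates = NULL,
                                       contrast = c("group", "mean"),
                                       q = 0.05) {
  contrast <- match.arg(contrast)
  x <- if (is.list(maps) && !is.data.frame(maps)) ppm_matrix(maps) else as.matrix(maps)
  if (nrow(x) < 3L) stop("need at least 3 subjects")
  if (any(apply(x, 2L, stats::sd) == 0)) stop("constant voxel column(s) in maps")
  V <- ncol(x)
  if (contrast == "mean") {
    mu <- mean(x)
    res <- t(apply(x, 2L, function(col) {
      tt <- stats::t.test(col, mu = mu)
      c(tt$statistic, tt$p.value)
    }))
  } else {
    if (is.null(groups)) stop("groups required for the group contrast")
    g <- factor(groups)
    if (nlevels(g) != 2L || min(table(g)) < 2L) {
      stop("group contrast needs two groups with >= 2 subjects each")
    }
    df0 <- data.frame(group = g)
    if (!is.null(covariates)) df0 <- cbind(df0, covariates)
    res <- t(apply(x, 2L, function(col) {
      d <- cbind(data.frame(y = col), df0)
      fit <- stats::lm(y ~ ., data = d)
      cf <- summary(fit)$coefficients
      row <- grep("^group", rownames(cf))[1]
      if (is.na(row)) stop("singular design: group term dropped")
      cf[row, c(3, 4)]
    }))
  }
  p_fdr <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(voxel = seq_len(V), t = res[, 1], p = res[, 2],
             p_fdr = p_fdr, significant = p_fdr < q, row.names = NULL)
}
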