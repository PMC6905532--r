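#' Z-score each voxel time series
#'
#' Transforms a masked V x T series so that every voxel (row) has mean 0 and
#' sample standard deviation 1, turning raw BOLD-like values into intrinsic
#' activation profiles: each voxel is measured against the ceiling and floor
#' of its own activation history rather than on an absolute scale.
#'
#' The sample (n - 1 denominator) standard deviation is used; at the tercile
#' level downstream this convention is immaterial, but it is fixed and
#' documented so results are reproducible to machine precision.
#'
#' @param series a `masked_series` object (see [masked_series()]) or a plain
#'   V x T numeric matrix.
#' @return an object of the same class with z-scored rows.
#' @export
zscore_voxels <- function(series) {
  x <- series_data(series)
  if (ncol(x) < 3L) stop("need at least 3 timepoints to z-score")
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad)) {
    stop("zero-variance voxel time series at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; constant voxels must be excluded at load time")
  }
  z <- (x - mu) / sdv
  series_set_data(series, z)
}

#' Tercile cut point of the standard normal
#'
#' The gaussian-threshold discretization cuts a z-scored series at plus/minus
#' the standard-normal quantile of 2/3 (about 0.431): under Gaussianity a
#' voxel spends a third of its time below, between and above the cuts.
#'
#' @return the positive cut point, `qnorm(2/3)`, at full precision.
#' @export
tercile_cut <- function() stats::qnorm(2 / 3)

#' Discretize intrinsic activation profiles into levels
#'
#' Recodes a z-scored V x T series into intrinsic activation levels (IALs)
#' in \{-1, 0, +1\} = \{Low, Neutral, High\}.
#'
#' Two modes are offered because fixed Gaussian cuts only give exact
#' equal-time occupancy under exact Gaussianity:
#' \describe{
#'   \item{`gaussian_threshold`}{fixed cuts at plus/minus [tercile_cut()]:
#'     z > cut is High (+1), z < -cut is Low (-1), otherwise Neutral (0).
#'     Values exactly equal to a cut are Neutral (deterministic tie rule).}
#'   \item{`empirical_tercile`}{each voxel's own time points are rank-split
#'     into three groups of size as equal as integers permit (the middle
#'     group takes the remainder), so per-voxel level occupancy is exactly
#'     1/3 within 1/T. Ties in value are broken by time index.}
#' }
#'
#' @param series z-scored `masked_series` or V x T matrix.
#' @param mode `"gaussian_threshold"` (default) or `"empirical_tercile"`.
#' @return an `ial_matrix`: list with `levels` (V x T integer matrix in
#'   \{-1,0,+1\}), `mode`, and `thresholds` (the (low, high) cut pair;
#'   `NA` in empirical mode where cuts are per voxel).
#' @export
discretize_ial <- function(series, mode = c("gaussian_threshold", "empirical_tercile")) {
  mode <- match.arg(mode)
  z <- series_data(series)
  V <- nrow(z); T <- ncol(z)
  lev <- matrix(0L, V, T)
  if (mode == "gaussian_threshold") {
    q <- tercile_cut()
    lev[z > q] <- 1L
    lev[z < -q] <- -1L
    thresholds <- c(low = -q, high = q)
  } else {
    n_low <- round(T / 3)
    n_high <- round(T / 3)
    for (v in seq_len(V)) {
      o <- order(z[v, ])                      # ties broken by time index
      lev[v, o[seq_len(n_low)]] <- -1L
      lev[v, o[seq.int(T - n_high + 1L, T)]] <- 1L
    }
    thresholds <- c(low = NA_real_, high = NA_real_)
  }
  structure(list(levels = lev, mode = mode, thresholds = thresholds),
            class = "ial_matrix")
}

#' Per-TR polarity proportions
#'
#' For each TR computes the proportion of voxels at each intrinsic activation
#' level: h(t) high (+1), l(t) low (-1), n(t) neutral (0). These length-T
#' series are the whole-brain summary on which the dynamic polarity regimes
#' are defined; by construction h + l + n = 1 at every TR.
#'
#' @param ial an `ial_matrix` or a V x T matrix over \{-1,0,+1\}.
#' @return a data.frame with columns `tr`, `h`, `l`, `n`.
#' @export
polarity_proportions <- function(ial) {
  lev <- if (inherits(ial, "ial_matrix")) ial$levels else ial
  if (!all(lev %in% c(-1L, 0L, 1L))) stop("levels must lie in {-1, 0, +1}")
  V <- nrow(lev)
  if (V < 1L) stop("need at least one voxel")
  h <- colMeans(lev == 1L)
  l <- colMeans(lev == -1L)
  n <- colMeans(lev == 0L)
  data.frame(tr = seq_len(ncol(lev)), h = h, l = l, n = n)
}

#' Scalar polarity metric
#'
#' Pi(t) = -(h_z(t) * l_z(t)), where h_z and l_z are the h(t) and l(t)
#' proportion series z-scored over the subject's own scan. Pi is large and
#' positive at TRs where one of h, l is far above 1/3 while the other is far
#' below (a polarized brain), near zero when the brain is balanced, and
#' negative when h and l deviate in the same direction.
#'
#' Z-scoring here uses the population (n denominator) standard deviation so
#' that the subject mean of Pi equals exactly -cor(h, l), a convenient
#' closed-form identity.
#'
#' @param props data.frame from [polarity_proportions()] (columns `h`, `l`).
#' @return numeric vector Pi(t) of length T.
#' @export
polarity_metric <- function(props) {
  h <- props$h; l <- props$l
  if (length(h) < 3L) stop("need at least 3 TRs")
  zs <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("constant proportion series; polarity metric undefined")
    (x - mean(x)) / s
  }
  -(zs(h) * zs(l))
}
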