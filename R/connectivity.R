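#' Band-pass filter network timecourses
#'
#' Zero-phase (forward-backward) Butterworth band-pass of each network
#' timecourse, defaulting to the [0.05, 0.15] Hz band and 5th order used
#' for resting-state network timecourses sampled at TR = 2 s.
#'
#' @param tcs networks x T matrix (or a single timecourse vector).
#' @param low_hz,high_hz band edges in Hz.
#' @param order filter order.
#' @param tr_seconds sampling interval in seconds.
#' @return filtered matrix of the same shape.
#' @export
bandpass_timecourses <- function(tcs, low_hz = 0.05, high_hz = 0.15,
                                 order = 5L, tr_seconds = 2) {
  vec <- is.null(dim(tcs))
  x <- if (vec) matrix(tcs, 1L) else as.matrix(tcs)
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  if (ncol(x) <= 3 * order) stop("timecourse too short for order-", order,
                                 " filtering")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
  if (vec) as.vector(out) else out
}

#' Tapered sliding-window weights
#'
#' Rectangular window convolved with a Gaussian (default sd 3 TRs), the
#' taper convention of sliding-window dynamic connectivity protocols;
#' the central `window_length` weights of the convolution are kept and
#' scaled to a maximum of 1.
#'
#' @param window_length window length in TRs.
#' @param gaussian_sd taper Gaussian sd in TRs; 0 gives an untapered
#'   rectangle.
#' @return weight vector of length `window_length`.
#' @export
window_taper <- function(window_length, gaussian_sd = 3) {
  if (gaussian_sd <= 0) return(rep(1, window_length))
  K <- ceiling(3 * gaussian_sd)
  g <- stats::dnorm(seq(-K, K), sd = gaussian_sd)
  full <- stats::convolve(rep(1, window_length), rev(g), type = "open")
  w <- full[seq.int(K + 1L, K + window_length)]
  w / max(w)
}

#' Sliding-window functional network connectivity
#'
#' Weighted Pearson correlations between all network pairs within tapered
#' windows advanced one TR at a time; T - window_length + 1 windows in all.
#' A window in which some network is constant has undefined correlations
#' for that network's pairs (returned as NA and flagged).
#'
#' @param tcs networks x T matrix of (band-passed) timecourses.
#' @param window_length window length in TRs (default 22).
#' @param gaussian_sd taper sd in TRs (default 3; 0 = untapered).
#' @return windows x pairs matrix with attributes `starts`,
#'   `window_length`, `taper` and `pairs` (2-column index matrix).
#' @export
sliding_window_fnc <- function(tcs, window_length = 22L, gaussian_sd = 3) {
  x <- as.matrix(tcs)
  n <- nrow(x); T <- ncol(x)
  if (T < window_length) stop("scan shorter than the window")
  if (n < 2L) stop("need at least two networks")
  w <- window_taper(window_length, gaussian_sd)
  starts <- seq_len(T - window_length + 1L)
  pr <- t(utils::combn(n, 2L))
  out <- matrix(NA_real_, length(starts), nrow(pr))
  for (i in seq_along(starts)) {
    seg <- x[, seq.int(starts[i], starts[i] + window_length - 1L), drop = FALSE]
    cw <- tryCatch(stats::cov.wt(t(seg), wt = w, cor = TRUE, method = "unbiased"),
                   error = function(e) NULL)
    if (!is.null(cw)) {
      cc <- cw$cor
      cc[!is.finite(cc)] <- NA_real_
      out[i, ] <- cc[pr]
    }
  }
  if (anyNA(out)) warning("window(s) with undefined correlations (constant network)")
  colnames(out) <- paste0("r", pr[, 1], "_", pr[, 2])
  structure(out, starts = starts, window_length = window_length,
            taper = w, pairs = pr)
}

#' Static functional network connectivity
#'
#' The one-window limit of [sliding_window_fnc()]: plain Pearson
#' correlations over the full untapered scan.
#'
#' @param tcs networks x T matrix.
#' @return named vector of pairwise correlations.
#' @export
static_fnc <- function(tcs) {
  x <- as.matrix(tcs)
  pr <- t(utils::combn(nrow(x), 2L))
  cc <- stats::cor(t(x))
  stats::setNames(cc[pr], paste0("r", pr[, 1], "_", pr[, 2]))
}

#' Cluster windowed connectivity vectors into dFNC states
#'
#' @param window_list list of per-subject windows x pairs matrices from
#'   [sliding_window_fnc()].
#' @param k number of connectivity states (default 5).
#' @param seed,replicates as in [fit_dpr()].
#' @return a `state_model` with per-subject window label sequences.
#' @export
fit_dfnc_states <- function(window_list, k = 5L, seed = 1L, replicates = 20L) {
  mats <- lapply(window_list, as.matrix)
  x <- do.call(rbind, mats)
  if (anyNA(x)) stop("windowed connectivity contains undefined correlations")
  fit <- kmeans_states(x, k, seed, replicates)
  lens <- vapply(mats, nrow, integer(1))
  idx <- split(seq_along(fit$cluster), rep(seq_along(mats), lens))
  labels <- lapply(idx, function(i) fit$cluster[i])
  names(labels) <- names(window_list)
  new_state_model(fit$centers, labels, k, seed)
}

#' Polarized-regime occupancy within dFNC-state windows
#'
#' For every sliding window, the polarized occupancy is the fraction of the
#' window's TRs assigned to a polarized regime (a window starting at TR s
#' spans TRs s .. s + window_length - 1). For each connectivity state and
#' group, a two-sample t-test compares the occupancies of that state's
#' windows against the occupancies of all windows, pooled over the group's
#' subjects: a positive t means polarization is elevated during that
#' connectivity state relative to the group's window-wise baseline.
#'
#' @param dpr_labels_list per-subject per-TR regime label sequences.
#' @param dfnc_labels_list per-subject per-window connectivity-state label
#'   sequences (aligned with windows starting at TR 1, step 1).
#' @param groups per-subject group labels.
#' @param window_length window length in TRs (default 22).
#' @param polarized regime labels counted as polarized (default 1:2).
#' @param q FDR level applied across (group, state) tests.
#' @return data.frame with columns `group`, `state`, `t`, `p`, `p_fdr`,
#'   `significant`, `n_windows` (NA rows where a state has no windows in a
#'   group).
#' @export
dpr_within_dfnc_test <- function(dpr_labels_list, dfnc_labels_list, groups,
                                 window_length = 22L, polarized = c(1L, 2L),
                                 q = 0.05) {
  stopifnot(length(dpr_labels_list) == length(dfnc_labels_list),
            length(groups) == length(dpr_labels_list))
  occ_list <- mapply(function(dpr, dfnc) {
    n_win <- length(dfnc)
    if (length(dpr) - window_length + 1L != n_win) {
      stop("window count does not match TR count minus window length + 1")
    }
    vapply(seq_len(n_win), function(s) {
      mean(dpr[seq.int(s, s + window_length - 1L)] %in% polarized)
    }, numeric(1))
  }, dpr_labels_list, dfnc_labels_list, SIMPLIFY = FALSE)
  k <- max(unlist(dfnc_labels_list))
  rows <- list()
  for (g in unique(groups)) {
    sel <- which(groups == g)
    occ <- unlist(occ_list[sel])
    lab <- unlist(dfnc_labels_list[sel])
    for (st in seq_len(k)) {
      in_state <- occ[lab == st]
      if (length(in_state) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(group = g, state = st,
                                                t = NA_real_, p = NA_real_,
                                                n_windows = length(in_state))
        next
      }
      # identical occupancy everywhere carries no signal: t = 0 by convention
      tt <- tryCatch(stats::t.test(in_state, occ),
                     error = function(e) list(statistic = 0, p.value = 1))
      rows[[length(rows) + 1L]] <- data.frame(group = g, state = st,
                                              t = unname(tt$statistic),
                                              p = tt$p.value,
                                              n_windows = length(in_state))
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < q
  out[, c("group", "state", "t", "p", "p_fdr", "significant", "n_windows")]
}

#' Nuisance-corrected regression of a per-subject measure
#'
#' Ordinary least squares of `response ~ predictor + covariates`, reporting
#' the predictor's coefficient and two-sided p-value. This is the engine
#' behind every group- and symptom-effect estimate: age, gender and mean
#' framewise displacement enter as nuisance covariates, and symptom-category
#' analyses additionally include the remaining symptom categories.
#'
#' @param response numeric per-subject response.
#' @param predictor the predictor of interest (numeric, or factor/character
#'   with two levels, e.g. group).
#' @param covariates data.frame of nuisance covariates (may be NULL).
#' @param response_id label carried into the output row.
#' @return one-row data.frame: `response`, `predictor`, `beta`, `t`, `p`.
#' @export
nuisance_regression <- function(response, predictor, covariates = NULL,
                                response_id = "response") {
  if (is.character(predictor)) predictor <- factor(predictor)
  d <- data.frame(y = response, pred = predictor)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  if (nrow(d) <= ncol(d)) stop("need more subjects than regressors")
  fit <- stats::lm(y ~ ., data = d)
  if (anyNA(stats::coef(fit))) stop("collinear design: coefficient(s) not estimable")
  cf <- summary(fit)$coefficients
  row <- grep("^pred", rownames(cf))[1]
  if (is.na(row)) stop("collinear design: predictor term dropped")
  pname <- if (is.factor(predictor)) {
    paste0(levels(predictor)[2], " vs ", levels(predictor)[1])
  } else "predictor"
  data.frame(response = response_id, predictor = pname,
             beta = cf[row, 1], t = cf[row, 3], p = cf[row, 4],
             row.names = NULL)
}

#' Symptom-category effect with cross-category correction
#'
#' Regresses a per-subject measure on one z-scored symptom category within
#' the patient group, with age, gender, meanFD and the remaining z-scored
#' symptom categories as covariates.
#'
#' @param response per-subject numeric values (patients only).
#' @param cohort patient rows of the cohort table (columns `age`, `gender`,
#'   `mean_fd`, `sympt_pos`, `sympt_neg`, `sympt_gen`).
#' @param symptom which category to test: `"sympt_pos"`, `"sympt_neg"` or
#'   `"sympt_gen"`.
#' @param response_id label for the output row.
#' @return one-row data.frame as [nuisance_regression()].
#' @export
symptom_effect <- function(response, cohort,
                           symptom = c("sympt_pos", "sympt_neg", "sympt_gen"),
                           response_id = "response") {
  symptom <- match.arg(symptom)
  all_sym <- c("sympt_pos", "sympt_neg", "sympt_gen")
  zs <- scale(as.matrix(cohort[, all_sym]))
  covs <- data.frame(age = cohort$age, gender = factor(cohort$gender),
                     mean_fd = cohort$mean_fd)
  others <- setdiff(all_sym, symptom)
  covs <- cbind(covs, as.data.frame(zs[, others, drop = FALSE]))
  nuisance_regression(response, zs[, symptom], covs, response_id)
}

#' Static-FNC regressions with and without the polarity covariate
#'
#' For every network pair (Fisher-z transformed correlations), fits
#' model A: `fnc ~ group + age + gender + meanFD` and
#' model B: `fnc ~ group + polarized occupancy + age + gender + meanFD`,
#' applying Benjamini-Hochberg FDR within each effect map. The summary
#' counts how many group effects significant under A survive under B —
#' the mediation signature is a large drop when group acts on connectivity
#' through polarization.
#'
#' @param fnc subjects x pairs matrix of static FNC correlations.
#' @param cohort data.frame with `group`, `age`, `gender`, `mean_fd`.
#' @param polarized_occupancy per-subject polarized-regime occupancy.
#' @param q FDR level.
#' @return list with `group_a`, `group_b`, `occupancy_b` effect tables and
#'   a `summary` data.frame (counts of significant pairs per map and the
#'   number of A-significant group effects lost under B).
#' @export
fnc_mediation_comparison <- function(fnc, cohort, polarized_occupancy,
                                     q = 0.05) {
  x <- as.matrix(fnc)
  stopifnot(nrow(x) == nrow(cohort),
            length(polarized_occupancy) == nrow(cohort))
  z <- atanh(pmin(pmax(x, -0.999999), 0.999999))
  covs <- data.frame(age = cohort$age, gender = factor(cohort$gender),
                     mean_fd = cohort$mean_fd)
  if (stats::sd(polarized_occupancy) == 0) {
    # a constant mediator cannot absorb anything; model B reduces to model A
    warning("polarized occupancy is constant across subjects; ",
            "model B equals model A")
    covs_b <- covs
  } else {
    covs_b <- cbind(covs, occupancy = polarized_occupancy)
  }
  fit_map <- function(covariates, predictor) {
    rows <- lapply(seq_len(ncol(z)), function(j) {
      nuisance_regression(z[, j], predictor, covariates,
                          response_id = colnames(x)[j] %||% paste0("pair", j))
    })
    tab <- do.call(rbind, rows)
    tab$p_fdr <- stats::p.adjust(tab$p, method = "BH")
    tab$significant <- tab$p_fdr < q
    tab
  }
  group_a <- fit_map(covs, factor(cohort$group))
  group_b <- fit_map(covs_b, factor(cohort$group))
  occ_b <- if (stats::sd(polarized_occupancy) == 0) NULL else {
    fit_map(cbind(covs, group = factor(cohort$group)), polarized_occupancy)
  }
  lost <- sum(group_a$significant & !group_b$significant)
  list(group_a = group_a, group_b = group_b, occupancy_b = occ_b,
       summary = data.frame(n_sig_group_a = sum(group_a$significant),
                            n_sig_group_b = sum(group_b$significant),
                            n_sig_occupancy_b = if (is.null(occ_b)) NA_integer_
                              else sum(occ_b$significant),
                            n_group_lost = lost))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
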