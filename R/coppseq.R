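#' One-hot channel encoding of a state label sequence
#'
#' Treats a symbolic state-occupancy time series over a k-letter alphabet as
#' a k-channel binary time series: channel j is 1 exactly at the timepoints
#' where state j is occupied, so every time column has exactly one 1. This
#' is the input form expected by multichannel convolutional sparse coding.
#'
#' @param labels length-T integer state sequence (values in 1..k).
#' @param k number of states/channels.
#' @return a `channel_series`: list with `channels` (k x T binary matrix)
#'   and `state_index_map` (channel -> state index).
#' @export
encode_channels <- function(labels, k) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > k)) {
    stop("labels out of range: all must lie in 1..", k)
  }
  ch <- matrix(0L, k, length(labels))
  ch[cbind(labels, seq_along(labels))] <- 1L
  structure(list(channels = ch, state_index_map = seq_len(k)),
            class = "channel_series")
}

#' Decode a channel series back to labels
#'
#' @param series a `channel_series`.
#' @return integer label sequence; `decode_channels(encode_channels(x, k))`
#'   equals `x`.
#' @export
decode_channels <- function(series) {
  apply(series$channels, 2L, which.max)
}

#' Per-element contributions and reconstruction for a convolutional dictionary
#'
#' Given a multichannel binary series, a dictionary of k-channel kernels of
#' common temporal width w, and per-element nonnegative activation
#' (coefficient) series, computes each element's total contribution (the
#' sum over time of its activation magnitudes — the natural summary when
#' coefficients are constrained nonnegative), the additive reconstruction
#' `sum_e kernel_e (*) coeff_e` (causal convolution, truncated to the input
#' length), and the reconstruction error. Dictionary learning itself is
#' delegated to external convolutional sparse coding solvers; this function
#' consumes their output.
#'
#' @param series a `channel_series` (k x T).
#' @param dictionary list of k x w numeric kernels.
#' @param coefficients list (same length) of length-T nonnegative
#'   activation series.
#' @return list with `totals` (per-element contribution), `reconstruction`
#'   (k x T matrix) and `rmse`.
#' @export
element_contributions <- function(series, dictionary, coefficients) {
  ch <- series$channels
  k <- nrow(ch); T <- ncol(ch)
  stopifnot(length(dictionary) == length(coefficients),
            length(dictionary) >= 1L)
  w <- ncol(dictionary[[1]])
  recon <- matrix(0, k, T)
  totals <- numeric(length(dictionary))
  for (e in seq_along(dictionary)) {
    ker <- dictionary[[e]]
    if (nrow(ker) != k) stop("kernel ", e, " has ", nrow(ker),
                             " channels; series has ", k)
    if (ncol(ker) != w) stop("kernels must share a common width")
    co <- coefficients[[e]]
    if (length(co) != T) stop("coefficient series ", e, " has length ",
                              length(co), "; expected ", T)
    if (any(co < 0)) stop("coefficients must be nonnegative")
    totals[e] <- sum(co)
    if (totals[e] > 0) {
      for (ci in seq_len(k)) {
        full <- stats::convolve(co, rev(ker[ci, ]), type = "open")
        recon[ci, ] <- recon[ci, ] + full[seq_len(T)]
      }
    }
  }
  rmse <- sqrt(mean((ch - recon)^2))
  list(totals = totals, reconstruction = recon, rmse = rmse)
}

#' Group effect on dictionary-element contributions
#'
#' Per-element nuisance-corrected regression of contribution totals on
#' group, with Benjamini-Hochberg FDR across elements. Constant-contribution
#' elements carry no information and are skipped with a warning.
#'
#' @param contributions subjects x elements matrix of contribution totals.
#' @param cohort data.frame with columns `group`, `age`, `gender`,
#'   `mean_fd` aligned with the rows of `contributions`.
#' @param q FDR level (default 0.05).
#' @return data.frame with columns `element`, `beta`, `p`, `p_fdr`,
#'   `significant` (NA rows for skipped elements).
#' @export
contribution_group_effect <- function(contributions, cohort, q = 0.05) {
  x <- as.matrix(contributions)
  stopifnot(nrow(x) == nrow(cohort))
  res <- lapply(seq_len(ncol(x)), function(e) {
    if (stats::sd(x[, e]) == 0) {
      warning("element ", e, " has constant contributions; skipped")
      return(c(NA_real_, NA_real_))
    }
    eff <- nuisance_regression(x[, e], predictor = cohort$group,
                               covariates = cohort[, c("age", "gender", "mean_fd")])
    c(eff$beta, eff$p)
  })
  res <- do.call(rbind, res)
  p_fdr <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(element = seq_len(ncol(x)), beta = res[, 1], p = res[, 2],
             p_fdr = p_fdr, significant = p_fdr < q)
}
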