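test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  T <- 160L; tr <- 2; t <- seq_len(T) * tr
  in_band <- sin(2 * pi * 0.1 * t)
  lo <- sin(2 * pi * 0.01 * t)
  amp <- function(x) sqrt(mean(x^2))
  y_in <- bandpass_timecourses(in_band, tr_seconds = tr)
  y_lo <- bandpass_timecourses(lo, tr_seconds = tr)
  # assess away from filter edge transients
  core <- 30:130
  expect_lt(abs(amp(y_in[core]) / amp(in_band[core]) - 1), 0.05)
  expect_lt(amp(y_lo[core]) / amp(lo[core]), 0.10)
  expect_equal(bandpass_timecourses(rep(0, T), tr_seconds = tr), rep(0, T))
  expect_error(bandpass_timecourses(in_band, low_hz = 0.05, high_hz = 0.4,
                                    tr_seconds = tr), "Nyquist")
  expect_error(bandpass_timecourses(in_band[1:10]), "too short")
})

test_that("sliding windows advance by one TR with tapered correlations", {
  T <- 100L
  x <- rbind(sin(seq_len(T) / 5), sin(seq_len(T) / 5))
  wc <- sliding_window_fnc(x, window_length = 22L)
  expect_equal(nrow(wc), T - 21L)
  expect_true(all(abs(wc[, 1] - 1) < 1e-10))
  expect_equal(attr(wc, "starts"), 1:(T - 21L))
  expect_length(attr(wc, "taper"), 22L)

  # independent white noise: windowed correlations center on zero
  set.seed(3)
  means <- replicate(10, {
    y <- matrix(rnorm(2 * 300L), 2L)
    mean(sliding_window_fnc(y, 22L)[, 1])
  })
  expect_lt(abs(mean(means)), 0.05)

  # constant network inside a window is flagged as undefined
  z <- rbind(c(rep(1, 30), rnorm(30)), rnorm(60))
  expect_warning(wcz <- sliding_window_fnc(z, 22L), "undefined")
  expect_true(anyNA(wcz))

  expect_error(sliding_window_fnc(x[, 1:10], 22L), "shorter")
})

test_that("static FNC is the untapered single-window limit", {
  set.seed(4)
  x <- matrix(rnorm(4 * 80L), 4L)
  st <- static_fnc(x)
  one <- sliding_window_fnc(x, window_length = 80L, gaussian_sd = 0)
  expect_equal(nrow(one), 1L)
  expect_equal(unname(one[1, ]), unname(st), tolerance = 1e-10)
  expect_equal(unname(st["r1_2"]), cor(x[1, ], x[2, ]))
})

test_that("connectivity-state clustering recovers planted window states", {
  set.seed(5)
  protos <- rbind(c(0.8, 0.8, 0), c(-0.6, 0.2, 0.6), c(0, -0.7, -0.7))
  wins <- lapply(1:4, function(s) {
    picks <- sample(1:3, 40L, replace = TRUE)
    m <- protos[picks, ] + matrix(rnorm(40L * 3L, 0, 0.05), 40L)
    attr(m, "picks") <- picks
    m
  })
  fit <- fit_dfnc_states(wins, k = 3L, seed = 2L, replicates = 5L)
  expect_lt(max(abs(rowSums(fit$occupancy) - 1)), 1e-12)
  # each planted state maps to exactly one recovered label
  for (s in 1:4) {
    tab <- table(attr(wins[[s]], "picks"), fit$labels[[s]])
    expect_true(all(rowSums(tab > 0) == 1L))
  }
  fit2 <- fit_dfnc_states(wins, k = 3L, seed = 2L, replicates = 5L)
  expect_identical(fit$labels, fit2$labels)
})

test_that("polarized occupancy within connectivity states is tested per group", {
  set.seed(6)
  T <- 100L; L <- 22L; n_win <- T - L + 1L
  # planted coupling: dFNC state 1 windows coincide with polarized blocks
  mk_subject <- function() {
    dpr <- rep(3L, T)
    blocks <- seq(10, 80, by = 30)
    for (b in blocks) dpr[b:(b + 12)] <- sample(1:2, 1L)
    occ_true <- sapply(seq_len(n_win), function(s)
      mean(dpr[s:(s + L - 1L)] %in% 1:2))
    dfnc <- ifelse(occ_true > median(occ_true), 1L, 2L)
    list(dpr = dpr, dfnc = dfnc)
  }
  subs <- lapply(1:6, function(i) mk_subject())
  res <- dpr_within_dfnc_test(lapply(subs, `[[`, "dpr"),
                              lapply(subs, `[[`, "dfnc"),
                              groups = rep(c("HC", "SZ"), 3L),
                              window_length = L)
  s1 <- res[res$state == 1L, ]
  expect_true(all(s1$t > 3))
  expect_true(all(s1$significant))

  # independence: labels unrelated to polarity give no survivors
  null_res <- replicate(5, {
    subs0 <- lapply(1:6, function(i) {
      list(dpr = sample(1:3, T, TRUE), dfnc = sample(1:2, n_win, TRUE))
    })
    r <- dpr_within_dfnc_test(lapply(subs0, `[[`, "dpr"),
                              lapply(subs0, `[[`, "dfnc"),
                              groups = rep(c("HC", "SZ"), 3L),
                              window_length = L)
    sum(r$significant)
  })
  expect_lte(mean(null_res > 0), 0.4)

  # identical occupancy in every window: t = 0 by convention
  subs_c <- lapply(1:2, function(i) {
    list(dpr = rep(1L, T), dfnc = rep(c(1L, 2L), length.out = n_win))
  })
  rc <- dpr_within_dfnc_test(lapply(subs_c, `[[`, "dpr"),
                             lapply(subs_c, `[[`, "dfnc"),
                             groups = c("HC", "HC"), window_length = L)
  expect_true(all(rc$t == 0))
})

test_that("nuisance regression recovers exact and null effects", {
  set.seed(7)
  n <- 40L
  pred <- rnorm(n)
  eff <- suppressWarnings(nuisance_regression(2 * pred, pred))
  expect_equal(eff$beta, 2, tolerance = 1e-8)
  expect_lt(eff$p, 1e-8)

  # null predictor: ~5% raw positives
  rate <- mean(replicate(200, {
    nuisance_regression(rnorm(n), rnorm(n),
                        covariates = data.frame(age = rnorm(n)))$p < 0.05
  }))
  expect_lt(abs(rate - 0.05), 0.04)

  # motion confound: a group difference carried entirely by meanFD vanishes
  # once meanFD is included
  fd <- c(rlnorm(20, log(0.1), 0.2), rlnorm(20, log(0.3), 0.2))
  grp <- rep(c("HC", "SZ"), each = 20L)
  y <- -2 * fd + rnorm(n, 0, 0.05)
  naive <- nuisance_regression(y, grp)
  corrected <- nuisance_regression(y, grp, covariates = data.frame(mean_fd = fd))
  expect_lt(naive$p, 0.001)
  expect_gt(corrected$p, 0.05)

  expect_error(nuisance_regression(rnorm(n), grp,
                                   covariates = data.frame(dup = grp)),
               "collinear")
  expect_error(nuisance_regression(rnorm(3), rnorm(3),
                                   covariates = data.frame(a = rnorm(3),
                                                           b = rnorm(3))),
               "more subjects")
})

test_that("symptom effects are corrected for the other categories", {
  set.seed(8)
  n <- 50L
  pos <- rnorm(n); neg <- 0.6 * pos + rnorm(n, 0, 0.8); gen <- rnorm(n)
  cohort <- data.frame(age = runif(n, 20, 60),
                       gender = sample(c("M", "F"), n, TRUE),
                       mean_fd = rlnorm(n, log(0.15), 0.3),
                       sympt_pos = pos, sympt_neg = neg, sympt_gen = gen)
  y <- -0.5 * scale(pos)[, 1] + rnorm(n, 0, 0.3)
  eff <- symptom_effect(y, cohort, "sympt_pos")
  expect_lt(eff$beta, 0)
  expect_lt(eff$p, 0.001)
  # the correlated negative category shows no independent effect
  eff_neg <- symptom_effect(y, cohort, "sympt_neg")
  expect_gt(eff_neg$p, 0.01)
})

test_that("polarity occupancy absorbs group effects in mediated FNC", {
  set.seed(9)
  n <- 60L; n_pairs <- 10L
  grp <- rep(c("HC", "SZ"), each = n / 2)
  occ <- ifelse(grp == "HC", 0.45, 0.30) + rnorm(n, 0, 0.04)
  # group acts on connectivity only through polarized occupancy
  fnc <- sapply(seq_len(n_pairs), function(j) tanh(1.5 * occ + rnorm(n, 0, 0.08)))
  colnames(fnc) <- paste0("p", seq_len(n_pairs))
  cohort <- data.frame(group = grp, age = runif(n, 20, 60),
                       gender = sample(c("M", "F"), n, TRUE),
                       mean_fd = rlnorm(n, log(0.15), 0.3))
  med <- fnc_mediation_comparison(fnc, cohort, occ)
  expect_gt(med$summary$n_sig_group_a, n_pairs / 2)
  expect_lt(med$summary$n_sig_group_b, med$summary$n_sig_group_a / 2)
  expect_gt(med$summary$n_sig_occupancy_b, n_pairs / 2)
  expect_gt(med$summary$n_group_lost, 0)

  # constant mediator: model B falls back to model A
  expect_warning(med_c <- fnc_mediation_comparison(fnc, cohort, rep(0.4, n)),
                 "constant")
  expect_equal(med_c$group_b$beta, med_c$group_a$beta)

  # null data: no survivors
  null_fnc <- matrix(tanh(rnorm(n * n_pairs, 0, 0.2)), n)
  med0 <- fnc_mediation_comparison(null_fnc, cohort, rnorm(n, 0.4, 0.05))
  expect_lte(med0$summary$n_sig_group_a, 1L)
})
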