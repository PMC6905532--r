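test_that("transition estimation pools counts within subjects only", {
  m <- estimate_transitions(list(c(1L, 1L, 2L)), k = 2L)
  expect_equal(m$counts, matrix(c(1, 0, 1, 0), 2L))
  expect_equal(m$matrix[1, ], c(0.5, 0.5))
  expect_equal(m$self_transition_probs[1], 0.5)
  # state 2 has no outgoing transitions -> undefined row
  expect_true(all(is.na(m$matrix[2, ])))
  expect_equal(m$undefined_rows, 2L)

  # the boundary between two subjects contributes no transition
  m2 <- estimate_transitions(list(c(1L, 1L), c(2L, 2L)), k = 2L)
  expect_equal(m2$counts[1, 2], 0)
  expect_equal(m2$counts[2, 1], 0)

  # observed rows sum to one
  set.seed(6)
  seqs <- lapply(1:4, function(i) sample.int(5L, 50L, replace = TRUE))
  m3 <- estimate_transitions(seqs, k = 5L)
  expect_lt(max(abs(rowSums(m3$matrix) - 1)), 1e-12)

  # averaged per-subject variant also yields stochastic rows
  m4 <- estimate_transitions(seqs, k = 5L, method = "average")
  expect_lt(max(abs(rowSums(m4$matrix) - 1)), 1e-12)
})

test_that("itinerary extraction follows argmax off-diagonal walks to a cycle", {
  P <- rbind(c(0, 1), c(1, 0))
  it <- most_probable_itinerary(P, 1L)
  expect_identical(it$transient, integer(0))
  expect_identical(it$orbit, c(1L, 2L))
  expect_equal(it$orbit_length, 2L)

  # planted 9-cycle recovered from every source
  P9 <- generate_transition_fixture(13L, "cycle", seed = 4L, orbit_length = 9L)
  for (src in c(1L, 5L, 9L, 13L)) {
    expect_equal(most_probable_itinerary(P9, src)$orbit_length, 9L)
  }
  # oscillation: period-2 orbit
  Po <- generate_transition_fixture(8L, "oscillation", seed = 4L)
  it2 <- most_probable_itinerary(Po, 7L)
  expect_equal(it2$orbit_length, 2L)
  expect_setequal(it2$orbit, c(1L, 2L))

  # absorbing dead-end row (no off-diagonal mass)
  Pd <- rbind(c(0, 1, 0), c(0, 1, 0), c(0.2, 0.3, 0.5))
  itd <- most_probable_itinerary(Pd, 1L)
  expect_true(itd$absorbing)
  expect_equal(itd$orbit_length, 0L)
  expect_identical(itd$transient, c(1L, 2L))
})

test_that("iterative extraction matches a brute-force oracle on random chains", {
  # oracle: build the deterministic successor map by sorting each row, then
  # replay the walk index by index
  oracle <- function(P, src) {
    k <- nrow(P)
    succ <- vapply(seq_len(k), function(i) {
      ord <- order(-P[i, ])
      ord[ord != i][1]
    }, integer(1))
    path <- src
    repeat {
      nxt <- succ[path[length(path)]]
      if (nxt %in% path) {
        entry <- match(nxt, path)
        return(list(transient = path[seq_len(entry - 1L)],
                    orbit = path[entry:length(path)]))
      }
      path <- c(path, nxt)
    }
  }
  for (s in 1:100) {
    set.seed(s)
    P <- matrix(runif(25), 5L); P <- P / rowSums(P)
    src <- sample.int(5L, 1L)
    it <- most_probable_itinerary(P, src)
    ref <- oracle(P, src)
    expect_identical(it$transient, as.integer(ref$transient))
    expect_identical(it$orbit, as.integer(ref$orbit))
    # pigeonhole: closes within k distinct steps
    expect_lte(length(it$transient) + it$orbit_length, 5L)
  }
})

test_that("group comparison reports orbits and polarized membership", {
  Pa <- generate_transition_fixture(6L, "cycle", seed = 2L, orbit_length = 4L)
  Pb <- generate_transition_fixture(6L, "oscillation", seed = 2L)
  ma <- estimate_transitions(list(c(1L, 2L)), k = 6L, group = "HC")
  ma$matrix <- Pa
  mb <- estimate_transitions(list(c(1L, 2L)), k = 6L, group = "SZ")
  mb$matrix <- Pb
  # polarized states sit inside the length-4 cycle (state 4) and outside the
  # 2-state oscillation, mirroring the healthy-vs-patient contrast
  cls <- factor(c("neutral", "neutral", "neutral", "negative", "neutral",
                  "positive"), levels = c("negative", "neutral", "positive"))
  report <- compare_group_itineraries(ma, mb, sources = c(1L, 6L),
                                   polarity_class = cls)
  expect_equal(nrow(report), 4L)
  hc <- report[report$group == "HC", ]
  sz <- report[report$group == "SZ", ]
  expect_true(all(hc$orbit_length == 4L))
  expect_true(all(sz$orbit_length == 2L))
  # the healthy cycle passes through polarized states; the oscillation not
  expect_true(all(hc$orbit_has_polarized))
  expect_false(any(sz$orbit_has_polarized))

  # identical models give identical itineraries
  same <- compare_group_itineraries(ma, ma, sources = 1:3)
  expect_equal(same[1:3, -1], same[4:6, -1], ignore_attr = TRUE)
})

test_that("healthy synthetic cohorts keep polarized states in their orbits", {
  sc <- small_cohort()
  copp <- fit_copps(sc$ials, k = 5L, seed = 3L, replicates = 5L)
  cls <- classify_copps(copp)
  by_group <- split(copp$labels, sc$cohort$group)
  trans <- lapply(names(by_group), function(g)
    estimate_transitions(by_group[[g]], k = copp$k, group = g))
  # both chains produce valid itineraries from every defined source
  for (m in trans) {
    defined <- setdiff(seq_len(copp$k), m$undefined_rows)
    for (src in defined) {
      it <- most_probable_itinerary(m, src)
      expect_lte(length(it$transient) + it$orbit_length, copp$k)
    }
  }
})
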