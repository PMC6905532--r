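#' Group-level state transition model
#'
#' Pools one-step transition counts over a group's subjects (scan
#' boundaries contribute no transitions) and row-normalizes into a
#' transition probability matrix. The diagonal (state-to-self) probability
#' is stored separately because itineraries are defined over distinct-state
#' transitions. An `"average"` method that averages per-subject
#' row-normalized matrices is also offered; pooling counts is the default.
#'
#' @param label_sequences list of per-subject integer state sequences.
#' @param k number of states (default: max observed label).
#' @param group optional group tag carried in the result.
#' @param method `"pooled"` (default) or `"average"`.
#' @return a `transition_model`: list with `matrix` (k x k, rows with at
#'   least one observed outgoing transition sum to 1; unobserved rows are
#'   NA and flagged in `undefined_rows`), `self_transition_probs`, `counts`,
#'   `group`, `method`.
#' @export
estimate_transitions <- function(label_sequences, k = NULL, group = NA,
                                 method = c("pooled", "average")) {
  method <- match.arg(method)
  stopifnot(is.list(label_sequences), length(label_sequences) >= 1L)
  if (is.null(k)) k <- max(unlist(label_sequences))
  count_one <- function(s) {
    cnt <- matrix(0, k, k)
    if (length(s) >= 2L) {
      from <- s[-length(s)]; to <- s[-1L]
      for (i in seq_along(from)) cnt[from[i], to[i]] <- cnt[from[i], to[i]] + 1
    }
    cnt
  }
  counts <- Reduce(`+`, lapply(label_sequences, count_one))
  norm_rows <- function(cnt) {
    rs <- rowSums(cnt)
    P <- cnt / ifelse(rs > 0, rs, NA)
    P[rs == 0, ] <- NA_real_
    P
  }
  P <- if (method == "pooled") {
    norm_rows(counts)
  } else {
    mats <- lapply(label_sequences, function(s) norm_rows(count_one(s)))
    arr <- simplify2array(mats)
    apply(arr, c(1, 2), mean, na.rm = TRUE)
  }
  undefined <- which(rowSums(counts) == 0)
  structure(list(matrix = P, self_transition_probs = diag(P),
                 counts = counts, group = group, method = method,
                 undefined_rows = undefined),
            class = "transition_model")
}

#' Most-probable distinct-state itinerary from a source state
#'
#' Repeatedly follows the most probable off-diagonal transition: from the
#' current state, move to the state with the largest transition probability
#' among the *other* states (self-transitions excluded, since itineraries
#' are over successive distinct states). The walk stops when a previously
#' visited state recurs; the visited sequence then splits into a transient
#' prefix and a closed periodic orbit containing the repeated state.
#' Argmax ties are broken deterministically by lowest state index. By the
#' pigeonhole principle every itinerary closes within k distinct steps.
#'
#' @param model a `transition_model` (or a plain row-stochastic matrix).
#' @param source starting state index.
#' @return an `itinerary`: list with `transient` (possibly empty integer
#'   vector), `orbit` (distinct-state cycle; empty if the walk hits an
#'   absorbing row with no off-diagonal mass), `orbit_length`, `absorbing`
#'   (TRUE when stopped by a dead-end row), `path` (full visited sequence).
#' @export
most_probable_itinerary <- function(model, source) {
  P <- if (inherits(model, "transition_model")) model$matrix else model
  k <- nrow(P)
  stopifnot(source >= 1L, source <= k)
  if (all(is.na(P[source, ]))) stop("source state ", source, " has an undefined row")
  visited <- integer(0)
  cur <- as.integer(source)
  repeat {
    if (cur %in% visited) {
      entry <- match(cur, visited)
      return(structure(list(transient = visited[seq_len(entry - 1L)],
                            orbit = visited[seq.int(entry, length(visited))],
                            orbit_length = length(visited) - entry + 1L,
                            absorbing = FALSE, path = c(visited, cur)),
                       class = "itinerary"))
    }
    visited <- c(visited, cur)
    row <- P[cur, ]
    row[cur] <- -Inf                       # distinct-state transitions only
    row[is.na(row)] <- -Inf
    if (all(row <= 0)) {
      return(structure(list(transient = visited, orbit = integer(0),
                            orbit_length = 0L, absorbing = TRUE,
                            path = visited),
                       class = "itinerary"))
    }
    cur <- which.max(row)                  # ties -> lowest index
  }
}

#' @export
print.itinerary <- function(x, ...) {
  cat("itinerary: transient [", paste(x$transient, collapse = " "),
      "] -> orbit (", paste(x$orbit, collapse = " "), "), period ",
      x$orbit_length, if (x$absorbing) " [absorbing dead-end]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Compare most-probable itineraries between two groups
#'
#' Extracts the itinerary from each source state under each group's
#' transition model and reports orbit lengths and whether each orbit
#' contains any strongly polarized state (per a CoPP classification).
#'
#' @param model_a,model_b `transition_model`s over the same state set.
#' @param sources integer vector of source states.
#' @param polarity_class optional factor from [classify_copps()] used to
#'   flag polarized orbit membership.
#' @return data.frame with one row per (source, group).
#' @export
compare_group_itineraries <- function(model_a, model_b, sources,
                                      polarity_class = NULL) {
  stopifnot(nrow(model_a$matrix) == nrow(model_b$matrix))
  one <- function(model, tag) {
    do.call(rbind, lapply(sources, function(s) {
      it <- most_probable_itinerary(model, s)
      pol <- if (is.null(polarity_class)) NA else {
        any(polarity_class[it$orbit] != "neutral")
      }
      data.frame(group = tag, source = s, orbit_length = it$orbit_length,
                 transient_length = length(it$transient),
                 orbit = paste(it$orbit, collapse = "-"),
                 orbit_has_polarized = pol, stringsAsFactors = FALSE)
    }))
  }
  ga <- if (!is.null(model_a$group) && !is.na(model_a$group)) model_a$group else "A"
  gb <- if (!is.null(model_b$group) && !is.na(model_b$group)) model_b$group else "B"
  rbind(one(model_a, ga), one(model_b, gb))
}
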