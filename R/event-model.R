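#' Define the event set of a z-score event-based model
#'
#' A disease "event" is a biomarker (regional volume, expressed as an
#' abnormality z-score relative to controls) crossing a fixed threshold.
#' With the default thresholds `c(1, 2)` every biomarker contributes two
#' events: subtle abnormality (z = 1) and atrophy (z = 2), so a model over
#' `B` biomarkers has `E = 2 B` events and stages `0..E`.
#'
#' @param biomarkers Character vector of biomarker (ROI) names.
#' @param thresholds Strictly increasing z-score thresholds shared by all
#'   biomarkers. Default `c(1, 2)`.
#' @param z_max Expected z-score at the final stage, after all of a
#'   biomarker's events have occurred. Must exceed `max(thresholds)`.
#'   Default 5.
#' @return An object of class `zs_event_set`: the event table (one row per
#'   event: biomarker, threshold level, z value), `B`, `E`, `z_max`.
#' @examples
#' es <- event_set(c("hippocampus", "temporal"))
#' es$E # 4 events
#' @export
event_set <- function(biomarkers, thresholds = c(1, 2), z_max = 5) {
  biomarkers <- as.character(biomarkers)
  assert_that(length(biomarkers) >= 1 && !anyDuplicated(biomarkers),
              "biomarkers must be unique, non-empty names")
  assert_that(length(thresholds) >= 1 && all(diff(thresholds) > 0) && all(thresholds > 0),
              "thresholds must be positive and strictly increasing")
  assert_that(z_max > max(thresholds), "z_max must exceed the largest threshold")
  B <- length(biomarkers)
  L <- length(thresholds)
  events <- tibble::tibble(
    event = seq_len(B * L),
    biomarker = rep(seq_len(B), each = L),
    roi = rep(biomarkers, each = L),
    level = rep(seq_len(L), times = B),
    z = rep(thresholds, times = B)
  )
  structure(
    list(biomarkers = biomarkers, thresholds = thresholds, z_max = z_max,
         events = events, B = B, L = L, E = B * L),
    class = "zs_event_set"
  )
}

#' @export
print.zs_event_set <- function(x, ...) {
  cat("<zs_event_set> ", x$B, " biomarkers x thresholds (",
      paste(x$thresholds, collapse = ", "), "), E = ", x$E,
      " events, z_max = ", x$z_max, "\n", sep = "")
  invisible(x)
}

# Positions (1-based rank in the sequence) of each event id.
sequence_positions <- function(sequence) {
  pos <- integer(length(sequence))
  pos[sequence] <- seq_along(sequence)
  pos
}

#' Check that an event ordering is a valid sequence
#'
#' A valid sequence is a permutation of all events in which, for every
#' biomarker, lower thresholds are reached before higher ones (z = 1
#' precedes z = 2).
#'
#' @param sequence Integer vector of event ids in order of occurrence.
#' @param events A [event_set()].
#' @return Logical scalar.
#' @export
is_valid_sequence <- function(sequence, events) {
  E <- events$E
  if (length(sequence) != E || !setequal(sequence, seq_len(E))) return(FALSE)
  pos <- sequence_positions(sequence)
  ev <- events$events
  all(vapply(split(pos[ev$event], ev$biomarker),
             function(p) !is.unsorted(p, strictly = TRUE), logical(1)))
}

# Draw a sequence uniformly over the valid orderings: permute all events,
# then sort each biomarker's events into threshold order within the slots
# they landed in.
random_sequence <- function(events) {
  ev <- events$events
  sequence <- sample.int(events$E)
  for (b in seq_len(events$B)) {
    ids <- ev$event[ev$biomarker == b]
    slots <- which(sequence %in% ids)
    sequence[slots] <- ids
  }
  sequence
}

#' Enumerate all valid event sequences
#'
#' Exhaustive enumeration of orderings that respect the within-biomarker
#' threshold order; for `B` biomarkers with 2 thresholds each there are
#' `(2B)! / 2^B` such orderings. Intended for small models (oracles, exact
#' optimization at B <= 2); refuses when `E > 10`.
#'
#' @inheritParams is_valid_sequence
#' @return A list of integer sequences.
#' @export
enumerate_sequences <- function(events) {
  assert_that(events$E <= 10,
              "enumerate_sequences is limited to E <= 10 events (combinatorial explosion)")
  ev <- events$events
  res <- list(integer(0))
  # Insert events one biomarker at a time; each biomarker's events keep their
  # threshold order, so we choose an increasing set of slots for them.
  for (b in seq_len(events$B)) {
    ids <- ev$event[ev$biomarker == b]
    new <- list()
    for (s in res) {
      n_new <- length(s) + length(ids)
      slot_sets <- utils::combn(n_new, length(ids), simplify = FALSE)
      for (slots in slot_sets) {
        out <- integer(n_new)
        out[slots] <- ids
        out[-slots] <- s
        new[[length(new) + 1L]] <- out
      }
    }
    res <- new
  }
  res
}

#' Expected biomarker trajectory along a sequence
#'
#' The model's expected abnormality z-score for one biomarker as a
#' piecewise-linear function of (possibly fractional) stage `t` in `[0, E]`:
#' it passes through `(0, 0)`, `(p_l, z_l)` at the 1-based position `p_l` of
#' each of the biomarker's threshold events, and `(E, z_max)`. When a
#' biomarker's last event occupies the final position the `z_max` anchor
#' takes precedence at `t = E`.
#'
#' @param sequence Integer event sequence.
#' @param events A [event_set()].
#' @param biomarker Biomarker name or index.
#' @param t Stage value(s) in `[0, E]`.
#' @return Numeric vector of expected z values, one per `t`.
#' @examples
#' es <- event_set(c("A", "B"))
#' s <- c(1, 3, 2, 4) # A1, B1, A2, B2
#' expected_trajectory(s, es, "A", t = 2) # 1.5
#' @export
expected_trajectory <- function(sequence, events, biomarker, t) {
  assert_that(is_valid_sequence(sequence, events), "invalid event sequence")
  if (is.character(biomarker)) biomarker <- match(biomarker, events$biomarkers)
  assert_that(!is.na(biomarker) && biomarker >= 1 && biomarker <= events$B,
              "unknown biomarker")
  assert_that(all(t >= 0 & t <= events$E), "stage t must lie in [0, E]")
  pos <- sequence_positions(sequence)
  ev <- events$events
  ids <- ev$event[ev$biomarker == biomarker]
  xs <- c(0, pos[ids], events$E)
  ys <- c(0, ev$z[match(ids, ev$event)], events$z_max)
  # later anchors win on ties (only possible at t = E)
  keep <- !duplicated(xs, fromLast = TRUE)
  stats::approx(xs[keep], ys[keep], xout = t, method = "linear")$y
}

# B x L matrix of each biomarker's event positions (columns = threshold
# levels, increasing along each row).
seq_pos_matrix <- function(sequence, events) {
  pos <- sequence_positions(sequence)
  matrix(pos[order(events$events$biomarker, events$events$level)],
         nrow = events$B, ncol = events$L, byrow = TRUE)
}

# (E+1) x B matrix of expected z values at integer stages 0..E (compiled
# piecewise-linear evaluation; expected_trajectory() is the definitional
# R-level counterpart).
trajectory_matrix <- function(sequence, events) {
  G <- traj_matrix_cpp(seq_pos_matrix(sequence, events), events$thresholds,
                       events$z_max, events$E)
  colnames(G) <- events$biomarkers
  G
}

# Coerce a z-score tibble (subject_id + one column per biomarker) or a bare
# matrix into the numeric matrix the likelihood kernel expects.
as_z_matrix <- function(z, events) {
  if (is.matrix(z)) {
    m <- z
    if (!is.null(colnames(m))) m <- m[, events$biomarkers, drop = FALSE]
  } else {
    z <- tibble::as_tibble(z)
    missing <- setdiff(events$biomarkers, names(z))
    assert_that(length(missing) == 0,
                paste0("z-score table lacks biomarker column(s): ",
                       paste(missing, collapse = ", ")))
    m <- as.matrix(z[, events$biomarkers])
    if ("subject_id" %in% names(z)) rownames(m) <- as.character(z$subject_id)
  }
  storage.mode(m) <- "double"
  assert_that(all(is.finite(m)), "z-scores must be finite")
  m
}

expand_sigma <- function(sigma, events) {
  sigma <- rep_len(as.double(sigma), events$B)
  assert_that(all(sigma > 0), "sigma must be positive")
  sigma
}

#' Marginal likelihood and stage posterior of subjects under one sequence
#'
#' Each subject's likelihood marginalizes a uniform stage prior over stages
#' `0..E`:
#' \deqn{P(x \mid S) = \frac{1}{E+1} \sum_{k=0}^{E} \prod_j
#'   N(x_j;\, g_j(S, k),\, \sigma_j)}
#' where `g_j(S, k)` is [expected_trajectory()] at stage `k`. Computation is
#' in the log domain throughout.
#'
#' @param z Z-score table (`subject_id` plus one column per biomarker) or a
#'   numeric matrix with biomarker columns.
#' @param sequence Integer event sequence.
#' @param events A [event_set()].
#' @param sigma Noise scale per biomarker (recycled). Default 1: the data
#'   are control-referenced z-scores, which fixes the noise scale.
#' @return A list: `log_marginal` (length n), `stage_posterior`
#'   (n x (E+1) matrix, rows sum to 1), `stage_loglik` (n x (E+1) matrix of
#'   per-stage log joint terms).
#' @export
sequence_likelihood <- function(z, sequence, events, sigma = 1) {
  assert_that(is_valid_sequence(sequence, events), "invalid event sequence")
  X <- as_z_matrix(z, events)
  assert_that(ncol(X) == events$B, "dimension mismatch between z and events")
  sigma <- expand_sigma(sigma, events)
  G <- trajectory_matrix(sequence, events)
  M <- stage_loglik_cpp(X, G, sigma)
  lse <- row_logsumexp(M)
  list(
    log_marginal = lse - log(events$E + 1),
    stage_posterior = exp(M - lse),
    stage_loglik = M
  )
}

# Weighted data log-likelihood of a sequence: sum_i w_i log P(x_i | S).
weighted_seq_loglik <- function(X, sequence, events, sigma, weights) {
  wseq_loglik_cpp(X, trajectory_matrix(sequence, events), sigma, weights)
}

#' Convert a sequence to a tidy event table
#'
#' @inheritParams is_valid_sequence
#' @return A tibble with `position`, `roi`, `level`, `z`.
#' @export
sequence_tbl <- function(sequence, events) {
  ev <- events$events[match(sequence, events$events$event), ]
  tibble::tibble(position = seq_along(sequence),
                 roi = ev$roi, level = ev$level, z = ev$z)
}

# Kendall rank correlation between two sequences' event positions; the
# standard score for agreement between a recovered and a true ordering.
#' Kendall tau between two event sequences
#'
#' Rank correlation of event positions; 1 means identical orderings, -1 a
#' fully reversed ordering.
#'
#' @param seq_a,seq_b Integer event sequences over the same event set.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
sequence_kendall_tau <- function(seq_a, seq_b) {
  assert_that(length(seq_a) == length(seq_b) && setequal(seq_a, seq_b),
              "sequences must cover the same events")
  stats::cor(sequence_positions(seq_a), sequence_positions(seq_b),
             method = "kendall")
}
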