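# Sequence optimization and mixture (subtype) fitting.

#' Fitting options for subtype models
#'
#' @param em_tol Convergence tolerance on the total log-likelihood gain per
#'   EM iteration. Default 1e-4.
#' @param em_maxit Maximum EM iterations. Default 100.
#' @param restarts Random initializations for a full sequence optimization
#'   (C = 1 fits and split halves at top level). Default 25.
#' @param em_restarts Random initializations inside EM M-steps, in addition
#'   to the warm start from the current sequence. Default 5.
#' @param split_restarts Random bipartitions tried per cluster when growing
#'   the model from C-1 to C subtypes. Default 5.
#' @param split_optim_restarts Sequence-optimization restarts used on each
#'   bipartition half. Default 3.
#' @param split_refine_rounds Hard-reassignment rounds refining each
#'   candidate bipartition before EM. Default 5.
#' @param empty_retries Bounded redraws when a bipartition half comes up
#'   empty. Default 20.
#' @return Named list of options.
#' @export
fit_options <- function(em_tol = 1e-4, em_maxit = 100, restarts = 25,
                        em_restarts = 5, split_restarts = 5,
                        split_optim_restarts = 3, split_refine_rounds = 5,
                        empty_retries = 20) {
  list(em_tol = em_tol, em_maxit = em_maxit, restarts = restarts,
       em_restarts = em_restarts, split_restarts = split_restarts,
       split_optim_restarts = split_optim_restarts,
       split_refine_rounds = split_refine_rounds,
       empty_retries = empty_retries)
}

# Valid insertion slots for event e given the sequence with e removed.
valid_slots <- function(seq_wo, e, events) {
  ev <- events$events
  b <- ev$biomarker[e]
  l <- ev$level[e]
  sibs <- ev$event[ev$biomarker == b]
  prev <- if (l > 1) sibs[l - 1] else NA_integer_
  nxt <- if (l < events$L) sibs[l + 1] else NA_integer_
  lo <- if (!is.na(prev)) match(prev, seq_wo) + 1L else 1L
  hi <- if (!is.na(nxt)) match(nxt, seq_wo) else length(seq_wo) + 1L
  lo:hi
}

insert_at <- function(seq_wo, e, slot) {
  append(seq_wo, e, after = slot - 1L)
}

# Greedy ascent by single-event relocation: remove each event in turn,
# reinsert at the best valid position, accept improvements; repeat passes
# until a full pass yields none. Monotone in the weighted log-likelihood.
local_search <- function(X, sequence, events, sigma, weights) {
  ll <- weighted_seq_loglik(X, sequence, events, sigma, weights)
  repeat {
    improved <- FALSE
    for (e in seq_len(events$E)) {
      seq_wo <- sequence[sequence != e]
      slots <- valid_slots(seq_wo, e, events)
      best_ll <- ll
      best_seq <- sequence
      for (s in slots) {
        cand <- insert_at(seq_wo, e, s)
        cll <- weighted_seq_loglik(X, cand, events, sigma, weights)
        if (cll > best_ll) {
          best_ll <- cll
          best_seq <- cand
        }
      }
      if (best_ll > ll) {
        ll <- best_ll
        sequence <- best_seq
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(sequence = sequence, loglik = ll)
}

optimize_sequence_x <- function(X, events, sigma, weights, restarts,
                                init = NULL) {
  assert_that(all(weights >= 0) && any(weights > 0),
              "subject weights must be non-negative with positive total")
  inits <- replicate(max(restarts, 1L), random_sequence(events),
                     simplify = FALSE)
  if (!is.null(init)) inits <- c(list(init), inits)
  best <- NULL
  for (s0 in inits) {
    res <- local_search(X, s0, events, sigma, weights)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  best
}

#' Maximum-likelihood event sequence for (weighted) subjects
#'
#' Finds the event ordering maximizing the weighted data log-likelihood
#' `sum_i w_i log P(x_i | S)` by greedy single-event relocation from random
#' valid initializations (best of `restarts` runs). The ascent never
#' decreases the weighted log-likelihood.
#'
#' @inheritParams sequence_likelihood
#' @param weights Per-subject weights in `[0, 1]` (EM responsibilities);
#'   default all 1.
#' @param restarts Number of random initializations. Default 25.
#' @param init Optional warm-start sequence, searched in addition to the
#'   random starts.
#' @param seed Optional seed (global RNG untouched).
#' @return List with `sequence` and `loglik`.
#' @export
optimize_sequence <- function(z, events, sigma = 1, weights = NULL,
                              restarts = 25, init = NULL, seed = NULL) {
  X <- as_z_matrix(z, events)
  sigma <- expand_sigma(sigma, events)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  assert_that(length(weights) == nrow(X), "one weight per subject is required")
  with_seed_if(seed, optimize_sequence_x(X, events, sigma, weights,
                                         restarts, init))
}

# n x C matrix of per-subject log marginal likelihoods under each sequence.
mixture_logmarg <- function(X, sequences, events, sigma) {
  lm <- vapply(sequences, function(s) {
    seq_logmarg_cpp(X, trajectory_matrix(s, events), sigma)
  }, numeric(nrow(X)))
  matrix(lm, nrow = nrow(X), ncol = length(sequences))
}

total_mixture_loglik <- function(LM, f) {
  sum(row_logsumexp(sweep(LM, 2, log(f), `+`)))
}

new_model <- function(sequences, f, events, sigma, loglik, R, n, trace,
                      iterations) {
  # deterministic subtype ordering: descending fraction, ties lexicographic
  key <- vapply(sequences, function(s) paste(sprintf("%03d", s), collapse = ""),
                character(1))
  ord <- order(-f, key)
  structure(
    list(C = length(sequences), sequences = sequences[ord],
         fractions = f[ord], events = events, sigma = sigma,
         loglik = loglik,
         responsibilities = R[, ord, drop = FALSE],
         n = n, loglik_trace = trace, iterations = iterations),
    class = "zs_model"
  )
}

#' Assemble a subtype model from known parameters
#'
#' Builds a `zs_model` directly from sequences and mixture fractions —
#' useful for staging new subjects under a previously fitted (or
#' ground-truth) model without refitting.
#'
#' @param sequences List of valid event sequences, one per subtype.
#' @param fractions Mixture fractions (simplex).
#' @param events A [event_set()].
#' @param sigma Noise scale per biomarker (recycled).
#' @return A `zs_model` (no responsibilities; fit metadata empty).
#' @export
subtype_model <- function(sequences, fractions, events, sigma = 1) {
  assert_that(length(sequences) == length(fractions),
              "one fraction per sequence is required")
  assert_that(all(fractions >= 0) && abs(sum(fractions) - 1) < 1e-9,
              "fractions must lie on the simplex (sum 1 within 1e-9)")
  for (s in sequences) {
    assert_that(is_valid_sequence(s, events), "invalid event sequence")
  }
  sigma <- expand_sigma(sigma, events)
  new_model(sequences, fractions, events, sigma, NA_real_,
            matrix(numeric(0), 0, length(sequences)), 0L, numeric(0), 0L)
}

#' @export
print.zs_model <- function(x, ...) {
  cat("<zs_model> ", x$C, " subtype(s), ", x$n, " subjects, log-likelihood ",
      format(x$loglik, digits = 8), "\n", sep = "")
  cat("fractions:", paste(format(x$fractions, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

em_fit <- function(X, sequences, f, events, sigma, opts) {
  C <- length(sequences)
  LM <- mixture_logmarg(X, sequences, events, sigma)
  ll <- total_mixture_loglik(LM, f)
  trace <- ll
  it <- 0L
  R <- row_softmax(sweep(LM, 2, log(f), `+`))
  while (it < opts$em_maxit) {
    it <- it + 1L
    R <- row_softmax(sweep(LM, 2, log(f), `+`))
    f <- colMeans(R)
    for (c in seq_len(C)) {
      res <- optimize_sequence_x(X, events, sigma, weights = R[, c],
                                 restarts = opts$em_restarts,
                                 init = sequences[[c]])
      sequences[[c]] <- res$sequence
      LM[, c] <- seq_logmarg_cpp(X, trajectory_matrix(res$sequence, events),
                                 sigma)
    }
    ll_new <- total_mixture_loglik(LM, f)
    trace <- c(trace, ll_new)
    gain <- ll_new - ll
    ll <- ll_new
    if (gain < opts$em_tol) break
  }
  R <- row_softmax(sweep(LM, 2, log(f), `+`))
  new_model(sequences, f, events, sigma, ll, R, nrow(X), trace, it)
}

# Two-way split of one cluster's members: random bipartition, then a few
# hard-reassignment rounds (optimize each half's sequence, reassign members
# to their better-fitting half) before handing the result to soft EM.
split_two <- function(Xm, events, sigma, opts) {
  grp <- NULL
  for (try in seq_len(opts$empty_retries)) {
    g <- runif(nrow(Xm)) < 0.5
    if (any(g) && !all(g)) {
      grp <- g
      break
    }
  }
  if (is.null(grp)) stop("could not draw a non-empty bipartition",
                         call. = FALSE)
  seqs <- list(NULL, NULL)
  for (round in seq_len(opts$split_refine_rounds)) {
    seqs <- lapply(list(grp, !grp), function(g) {
      optimize_sequence_x(Xm[g, , drop = FALSE], events, sigma,
                          weights = rep(1, sum(g)),
                          restarts = opts$split_optim_restarts)$sequence
    })
    LM <- mixture_logmarg(Xm, seqs, events, sigma)
    grp_new <- LM[, 1] >= LM[, 2]
    if (!any(grp_new) || all(grp_new) || identical(grp_new, grp)) break
    grp <- grp_new
  }
  list(sequences = seqs, sizes = c(sum(grp), sum(!grp)))
}

# Grow a (C-1)-subtype model to C subtypes: try random two-way splits of each
# cluster's hard-assigned members, keep the initialization with the best
# total likelihood, then run EM.
split_and_em <- function(X, prev, events, sigma, opts) {
  hard <- max.col(prev$responsibilities, ties.method = "first")
  best <- NULL
  for (c in seq_len(prev$C)) {
    members <- which(hard == c)
    if (length(members) < 2) next
    for (r in seq_len(opts$split_restarts)) {
      sp <- split_two(X[members, , drop = FALSE], events, sigma, opts)
      cand_seqs <- c(prev$sequences[-c], sp$sequences)
      cand_f <- c(prev$fractions[-c],
                  prev$fractions[c] * sp$sizes / length(members))
      LM <- mixture_logmarg(X, cand_seqs, events, sigma)
      ll <- total_mixture_loglik(LM, cand_f)
      if (is.null(best) || ll > best$ll) {
        best <- list(seqs = cand_seqs, f = cand_f, ll = ll)
      }
    }
  }
  if (is.null(best)) stop("no cluster large enough to split", call. = FALSE)
  em_fit(X, best$seqs, best$f, events, sigma, opts)
}

fit_path <- function(X, C_max, events, sigma, opts) {
  models <- vector("list", C_max)
  s1 <- optimize_sequence_x(X, events, sigma, weights = rep(1, nrow(X)),
                            restarts = opts$restarts)
  models[[1]] <- new_model(list(s1$sequence), 1, events, sigma, s1$loglik,
                           matrix(1, nrow(X), 1), nrow(X), s1$loglik, 0L)
  if (C_max > 1) {
    for (C in 2:C_max) {
      models[[C]] <- split_and_em(X, models[[C - 1]], events, sigma, opts)
    }
  }
  models
}

#' Fit a mixture of event sequences (atrophy subtypes)
#'
#' Fits `C` latent subtypes, each one event ordering with a mixture fraction,
#' by hierarchical model growing: the `C`-subtype model is initialized by
#' two-way splitting a cluster of the `(C-1)`-subtype model (best random
#' bipartition after optimizing each half), then refined by EM. The E-step
#' computes responsibilities `r_ic` proportional to `f_c P(x_i | S_c)`; the
#' M-step sets `f_c` to the mean responsibility and re-optimizes each
#' sequence under weights `r_ic` (warm-started, so the total log-likelihood
#' `sum_i log sum_c f_c P(x_i | S_c)` never decreases). Reported subtypes are
#' ordered by descending fraction (ties broken lexicographically).
#'
#' @inheritParams optimize_sequence
#' @param C Number of subtypes, `1 <= C <= n_max`.
#' @param n_max Hard cap on the number of subtypes. Default 4.
#' @param options A [fit_options()] list.
#' @return A `zs_model`: sequences, fractions, total log-likelihood,
#'   responsibilities, EM trace.
#' @export
fit_subtypes <- function(z, C, events, sigma = 1, n_max = 4L,
                         options = fit_options(), seed = NULL) {
  assert_that(C >= 1 && C <= n_max,
              paste0("C must lie in 1..n_max (= ", n_max, ")"))
  X <- as_z_matrix(z, events)
  sigma <- expand_sigma(sigma, events)
  with_seed_if(seed, fit_path(X, C, events, sigma, options)[[C]])
}
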