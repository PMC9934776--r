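#' MCMC sampling of sequence uncertainty
#'
#' Per subtype, a Metropolis random walk over valid event orderings:
#' proposals relocate one uniformly chosen event to a uniformly chosen valid
#' position (the proposal is symmetric, so acceptance is
#' `min(1, likelihood ratio)`). The likelihood is the responsibility-weighted
#' data log-likelihood with responsibilities frozen at the fitted model's
#' values — the sampler explores sequence space only. Positional probability
#' matrices (the positional variance diagram) are computed from thinned
#' post-burn-in samples; because every sample places each event at exactly
#' one position, the matrices are doubly stochastic.
#'
#' @inheritParams optimize_sequence
#' @param model A fitted [fit_subtypes()] model.
#' @param n_iter Total iterations per subtype. Default 100000.
#' @param burn_in Burn-in iterations discarded before summarizing. Default
#'   10000; must be `< n_iter`.
#' @param thin Keep every `thin`-th post-burn-in sample. Default 10.
#' @return A `zs_trace`: per subtype, thinned sampled sequences with their
#'   log-likelihoods, acceptance rate, and the `E x E` positional probability
#'   matrix `P[event, position]` (rows ordered as in the event set).
#' @export
mcmc_sequences <- function(z, model, n_iter = 100000, burn_in = 10000,
                           thin = 10, seed = NULL) {
  stopifnot(inherits(model, "zs_model"))
  assert_that(n_iter > burn_in && burn_in >= 0,
              "need n_iter > burn_in >= 0")
  events <- model$events
  X <- as_z_matrix(z, events)
  assert_that(nrow(X) == nrow(model$responsibilities),
              "z and the fitted model cover different subjects")
  with_seed_if(seed, {
    chains <- purrr::map(seq_len(model$C), function(c) {
      w <- model$responsibilities[, c]
      cur <- model$sequences[[c]]
      cur_ll <- weighted_seq_loglik(X, cur, events, model$sigma, w)
      keep_idx <- seq(burn_in + thin, n_iter, by = thin)
      samples <- matrix(0L, length(keep_idx), events$E)
      lls <- numeric(length(keep_idx))
      accepted <- 0L
      k <- 0L
      for (it in seq_len(n_iter)) {
        e <- sample.int(events$E, 1)
        seq_wo <- cur[cur != e]
        slots <- valid_slots(seq_wo, e, events)
        cand <- insert_at(seq_wo, e, slots[sample.int(length(slots), 1)])
        cand_ll <- weighted_seq_loglik(X, cand, events, model$sigma, w)
        if (log(runif(1)) <= cand_ll - cur_ll) {
          cur <- cand
          cur_ll <- cand_ll
          accepted <- accepted + 1L
        }
        if (it > burn_in && (it - burn_in) %% thin == 0) {
          k <- k + 1L
          samples[k, ] <- cur
          lls[k] <- cur_ll
        }
      }
      P <- matrix(0, events$E, events$E,
                  dimnames = list(event = NULL, position = NULL))
      for (i in seq_len(nrow(samples))) {
        pos <- sequence_positions(samples[i, ])
        P[cbind(seq_len(events$E), pos)] <- P[cbind(seq_len(events$E), pos)] + 1
      }
      P <- P / nrow(samples)
      list(samples = samples, loglik = lls,
           acceptance_rate = accepted / n_iter, positional = P)
    })
    structure(list(chains = chains, events = events, C = model$C,
                   n_iter = n_iter, burn_in = burn_in, thin = thin),
              class = "zs_trace")
  })
}

#' @export
print.zs_trace <- function(x, ...) {
  acc <- vapply(x$chains, `[[`, numeric(1), "acceptance_rate")
  cat("<zs_trace> ", x$C, " subtype chain(s), ", x$n_iter, " iterations (",
      x$burn_in, " burn-in, thin ", x$thin, ")\n", sep = "")
  cat("acceptance:", paste(format(acc, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Modal (most frequently sampled) sequence of an MCMC chain
#'
#' @param trace A [mcmc_sequences()] result.
#' @param subtype Subtype index.
#' @return Integer event sequence.
#' @export
modal_sequence <- function(trace, subtype = 1) {
  s <- trace$chains[[subtype]]$samples
  key <- apply(s, 1, paste, collapse = ",")
  as.integer(strsplit(names(which.max(table(key))), ",")[[1]])
}

#' Positional probability matrices as a tidy table
#'
#' @param trace A [mcmc_sequences()] result.
#' @return Tibble with `subtype`, `roi`, `level`, `z`, `position`,
#'   `probability`.
#' @export
positional_probabilities <- function(trace) {
  ev <- trace$events$events
  purrr::map_dfr(seq_len(trace$C), function(c) {
    P <- trace$chains[[c]]$positional
    tibble::tibble(
      subtype = c,
      roi = rep(ev$roi, times = ncol(P)),
      level = rep(ev$level, times = ncol(P)),
      z = rep(ev$z, times = ncol(P)),
      position = rep(seq_len(ncol(P)), each = nrow(P)),
      probability = as.vector(P)
    )
  })
}
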