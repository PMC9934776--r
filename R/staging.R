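#' Assign maximum-likelihood subtype and stage
#'
#' For each subject, the subtype posterior is proportional to
#' `f_c P(x | S_c)`; the candidate subtype is its argmax, and the stage is
#' the argmax of the stage posterior conditional on that subtype (ties in
#' either argmax go to the lowest index). Subjects whose maximum-likelihood
#' stage is 0 are recorded as subtype zero (`ml_subtype = 0`) — their data
#' carry no evidence of any event — with the candidate subtype retained in
#' `candidate_subtype`. The alternative literal rule assigns subtype zero
#' whenever every z-score is below the first event threshold.
#'
#' @inheritParams mcmc_sequences
#' @param rule Subtype-zero rule: `"ml_stage"` (default; subtype zero iff the
#'   ML stage is 0) or `"max_z"` (subtype zero, at stage 0, iff all z-scores
#'   are below the smallest event threshold).
#' @return Tibble with one row per subject: `subject_id`, `ml_subtype`
#'   (0..C), `ml_stage` (0..E), `candidate_subtype`, subtype posterior
#'   columns `p_subtype_c`, and list-column `stage_posterior` (probabilities
#'   over stages 0..E under the candidate subtype). `ml_subtype == 0` iff
#'   `ml_stage == 0`.
#' @export
assign_subtypes <- function(z, model, rule = c("ml_stage", "max_z")) {
  stopifnot(inherits(model, "zs_model"))
  rule <- match.arg(rule)
  events <- model$events
  X <- as_z_matrix(z, events)
  n <- nrow(X)
  LM <- mixture_logmarg(X, model$sequences, events, model$sigma)
  post <- row_softmax(sweep(LM, 2, log(model$fractions), `+`))
  candidate <- max.col(post, ties.method = "first")
  stage_posts <- lapply(model$sequences, function(s) {
    sequence_likelihood(X, s, events, model$sigma)$stage_posterior
  })
  ml_stage <- integer(n)
  stage_posterior <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- stage_posts[[candidate[i]]][i, ]
    stage_posterior[[i]] <- sp
    ml_stage[i] <- which.max(sp) - 1L
  }
  ml_subtype <- candidate
  if (rule == "ml_stage") {
    ml_subtype[ml_stage == 0L] <- 0L
  } else {
    sub0 <- apply(X, 1, max) < min(events$thresholds)
    ml_subtype[sub0] <- 0L
    ml_stage[sub0] <- 0L
    # keep the subtype-zero <-> stage-zero equivalence under the literal rule
    ml_subtype[ml_stage == 0L] <- 0L
  }
  ids <- rownames(X) %||% as.character(seq_len(n))
  out <- tibble::tibble(subject_id = ids, ml_subtype = ml_subtype,
                        ml_stage = ml_stage, candidate_subtype = candidate)
  colnames(post) <- paste0("p_subtype_", seq_len(model$C))
  out <- dplyr::bind_cols(out, tibble::as_tibble(post))
  out$stage_posterior <- stage_posterior
  out
}

#' Counts of stage assignments per subtype
#'
#' Contingency counts over the full (subtype, stage) grid, for stage
#' heatmaps.
#'
#' @param assignments An [assign_subtypes()] tibble.
#' @param E Number of events (stage range 0..E); inferred from the data when
#'   omitted.
#' @return Tibble with `ml_subtype`, `ml_stage`, `n` (zero-filled grid).
#' @export
stage_counts <- function(assignments, E = max(assignments$ml_stage)) {
  assert_that(nrow(assignments) > 0, "no assignment records")
  grid <- tidyr::expand_grid(
    ml_subtype = sort(unique(assignments$ml_subtype)),
    ml_stage = 0:E
  )
  counts <- dplyr::count(assignments, .data$ml_subtype, .data$ml_stage)
  out <- dplyr::left_join(grid, counts, by = c("ml_subtype", "ml_stage"))
  out$n[is.na(out$n)] <- 0L
  out
}

#' Per-subtype stage medians and interquartile ranges
#'
#' @inheritParams stage_counts
#' @return Tibble with `ml_subtype`, `n`, `median_stage`, `q1`, `q3`.
#' @export
stage_summary <- function(assignments) {
  assert_that(nrow(assignments) > 0, "no assignment records")
  dplyr::summarise(
    dplyr::group_by(assignments, .data$ml_subtype),
    n = dplyr::n(),
    median_stage = median(.data$ml_stage),
    q1 = unname(quantile(.data$ml_stage, 0.25)),
    q3 = unname(quantile(.data$ml_stage, 0.75)),
    .groups = "drop"
  )
}
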