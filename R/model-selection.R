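#' Choose the number of subtypes by cross-validated information criterion
#'
#' K-fold cross-validation over subjects: for every candidate number of
#' subtypes `C` in `1..n_max` and every fold, the mixture model is fitted on
#' the training subjects and the held-out subjects' log mixture likelihood
#' `sum_i log sum_c f_c P(x_i | S_c)` is evaluated at the fitted
#' maximum-likelihood point. The criterion is
#' `CVIC(C) = -2 * sum_folds (test log-likelihood)`; the selected model is
#' the `C` minimizing CVIC (ties go to the smaller `C`). Out-of-sample
#' evaluation penalizes superfluous subtypes implicitly; there is no explicit
#' complexity term. Folds are drawn uniformly at random keyed by subject id
#' (sorted before assignment), so the fold map — and hence the CVIC — is
#' invariant to the row order of `z`.
#'
#' @inheritParams fit_subtypes
#' @param n_max Largest number of subtypes considered. Default 4.
#' @param folds Number of cross-validation folds (>= 2). Default 10.
#' @return A `zs_cv`: per-C CVIC and per-fold test log-likelihoods,
#'   `selected_C`, and the fold assignment.
#' @export
run_cv <- function(z, events, n_max = 4L, folds = 10L, sigma = 1,
                   options = fit_options(), seed = NULL) {
  assert_that(folds >= 2, "at least 2 folds are required")
  X <- as_z_matrix(z, events)
  n <- nrow(X)
  assert_that(n >= folds, "need at least as many subjects as folds")
  sigma <- expand_sigma(sigma, events)
  ids <- rownames(X) %||% as.character(seq_len(n))
  with_seed_if(seed, {
    ord <- order(ids)
    fold_sorted <- sample(rep_len(seq_len(folds), n))
    fold <- integer(n)
    fold[ord] <- fold_sorted
    test_ll <- matrix(NA_real_, folds, n_max,
                      dimnames = list(fold = NULL, C = NULL))
    for (k in seq_len(folds)) {
      tr <- X[fold != k, , drop = FALSE]
      te <- X[fold == k, , drop = FALSE]
      path <- fit_path(tr, n_max, events, sigma, options)
      for (C in seq_len(n_max)) {
        LM <- mixture_logmarg(te, path[[C]]$sequences, events, sigma)
        test_ll[k, C] <- total_mixture_loglik(LM, path[[C]]$fractions)
      }
    }
    cvic <- -2 * colSums(test_ll)
    structure(
      list(cvic = cvic, test_loglik = test_ll,
           selected_C = which.min(cvic),
           fold = tibble::tibble(subject_id = ids, fold = fold),
           n_max = n_max, folds = folds, seed = seed),
      class = "zs_cv"
    )
  })
}

#' @export
print.zs_cv <- function(x, ...) {
  cat("<zs_cv> ", x$folds, "-fold cross-validation, C = 1..", x$n_max,
      "\n", sep = "")
  print(tibble::tibble(C = seq_len(x$n_max), CVIC = x$cvic,
                       selected = seq_len(x$n_max) == x$selected_C))
  invisible(x)
}
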