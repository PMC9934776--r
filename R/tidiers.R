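# broom-style tidiers for fitted objects.

#' Tidy a fitted subtype model
#'
#' @param x A `zs_model`.
#' @param ... Unused.
#' @return Tibble with `subtype`, `fraction`, `position`, `roi`, `level`,
#'   `z`: each subtype's event ordering, one row per event.
#' @method tidy zs_model
#' @export
tidy.zs_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$C), function(c) {
    dplyr::mutate(sequence_tbl(x$sequences[[c]], x$events),
                  subtype = c, fraction = x$fractions[c],
                  .before = 1)
  })
}

#' Glance at a fitted subtype model
#'
#' @inheritParams tidy.zs_model
#' @return One-row tibble: `n_subtypes`, `n_subjects`, `n_events`,
#'   `loglik`, `em_iterations`.
#' @method glance zs_model
#' @export
glance.zs_model <- function(x, ...) {
  tibble::tibble(n_subtypes = x$C, n_subjects = x$n, n_events = x$events$E,
                 loglik = x$loglik, em_iterations = x$iterations)
}

#' Tidy an MCMC sequence trace
#'
#' @param x A `zs_trace`.
#' @param ... Unused.
#' @return The positional-probability table of [positional_probabilities()].
#' @method tidy zs_trace
#' @export
tidy.zs_trace <- function(x, ...) positional_probabilities(x)

#' Glance at an MCMC sequence trace
#'
#' @inheritParams tidy.zs_trace
#' @return Tibble with one row per subtype chain: `subtype`,
#'   `acceptance_rate`, `n_samples`.
#' @method glance zs_trace
#' @export
glance.zs_trace <- function(x, ...) {
  tibble::tibble(
    subtype = seq_len(x$C),
    acceptance_rate = vapply(x$chains, `[[`, numeric(1), "acceptance_rate"),
    n_samples = vapply(x$chains, function(ch) nrow(ch$samples), integer(1))
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `zs_cv`.
#' @param ... Unused.
#' @return Tibble with `n_subtypes`, `cvic`, `selected`.
#' @method tidy zs_cv
#' @export
tidy.zs_cv <- function(x, ...) {
  tibble::tibble(n_subtypes = seq_len(x$n_max), cvic = x$cvic,
                 selected = seq_len(x$n_max) == x$selected_C)
}

#' Glance at a cross-validation result
#'
#' @inheritParams tidy.zs_cv
#' @return One-row tibble: `selected_C`, `folds`, `min_cvic`.
#' @method glance zs_cv
#' @export
glance.zs_cv <- function(x, ...) {
  tibble::tibble(selected_C = x$selected_C, folds = x$folds,
                 min_cvic = min(x$cvic))
}

#' Tidy a longitudinal mixed-model fit
#'
#' @param x A `zs_lme`.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `se`, `conf_low`,
#'   `conf_high`, `p_value`).
#' @method tidy zs_lme
#' @export
tidy.zs_lme <- function(x, ...) x$coefficients

#' Glance at a longitudinal mixed-model fit
#'
#' @inheritParams tidy.zs_lme
#' @return One-row tibble with sizes, variance components, log-likelihood
#'   and convergence flags.
#' @method glance zs_lme
#' @export
glance.zs_lme <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_obs = x$n_obs,
                 sigma_b = x$sigma_b, sigma_e = x$sigma_e,
                 loglik = x$loglik, converged = x$converged,
                 singular = x$singular, method = x$method)
}

#' Tidy a control GLM
#'
#' @param x A `zs_control_glm`.
#' @param ... Unused.
#' @return The per-ROI coefficient tibble.
#' @method tidy zs_control_glm
#' @export
tidy.zs_control_glm <- function(x, ...) x$coefficients
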