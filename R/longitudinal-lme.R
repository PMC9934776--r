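#' Linear mixed model of longitudinal cognitive decline by subtype
#'
#' Fits, by maximum likelihood, the random-intercept model
#' `score_ij = b0 + b_age age_i + gamma_c + (delta_0 + delta_c) t_ij + u_i + e_ij`
#' with participant-specific random intercepts `u_i`: fixed effects are
#' baseline age, time since baseline (continuous), subtype main effects and
#' subtype-by-time interactions, with subtype zero as the reference group.
#' Observations beyond `horizon_yrs` are excluded to keep a comparable
#' observation window. Inference is by Wald normal approximation (95% CIs
#' and two-sided p-values); with cohorts in the hundreds no small-sample
#' degrees-of-freedom correction is applied.
#'
#' Degenerate noise-free data (zero residual variance) are detected and fit
#' exactly by least squares; non-convergence and singular fits (random-
#' intercept variance at the boundary) are flagged in the result, never
#' raised as errors.
#'
#' @param data Long tibble with `subject_id`, `time` (yrs since baseline),
#'   `value`, `baseline_age`, `subtype` (0 = reference), and optionally a
#'   `score` column when several outcomes share the table.
#' @param score Outcome name to filter on when `data$score` exists.
#' @param horizon_yrs Observation window; visits after it are dropped.
#'   Default 4.
#' @param include_main_effects Include subtype main effects alongside the
#'   interactions (default TRUE; omitting them biases the interaction slopes
#'   when baseline levels differ by subtype).
#' @param reml Use REML instead of ML. Default FALSE (ML keeps likelihoods
#'   comparable across fixed-effect structures).
#' @return A `zs_lme`: coefficient tibble (`term`, `estimate`, `se`,
#'   `conf_low`, `conf_high`, `p_value`), variance components `sigma_b` /
#'   `sigma_e`, `loglik`, sizes, `converged` / `singular` flags, and the
#'   underlying fit.
#' @export
fit_decline_lme <- function(data, score = NULL, horizon_yrs = 4,
                            include_main_effects = TRUE, reml = FALSE) {
  data <- tibble::as_tibble(data)
  if (!is.null(score) && "score" %in% names(data)) {
    data <- dplyr::filter(data, .data$score == !!score)
  }
  need <- c("subject_id", "time", "value", "baseline_age", "subtype")
  missing_cols <- setdiff(need, names(data))
  assert_that(length(missing_cols) == 0,
              paste("data lacks columns:", paste(missing_cols, collapse = ", ")))
  data <- dplyr::filter(data, .data$time <= horizon_yrs, !is.na(.data$value))
  nv <- table(data$subject_id)
  assert_that(sum(nv >= 2) >= 10,
              "need at least 10 subjects with 2 or more visits")
  data$subtype <- stats::relevel(factor(data$subtype), ref = "0")
  fixed_form <- if (include_main_effects) {
    value ~ baseline_age + subtype + time + subtype:time
  } else {
    value ~ baseline_age + time + subtype:time
  }
  form <- stats::update(fixed_form, . ~ . + (1 | subject_id))

  # exact-interpolation guard: with (near-)zero residual variation the mixed
  # model is degenerate and plain least squares is the exact ML fit
  ols <- lm(fixed_form, data = data)
  ols_sd <- sqrt(sum(stats::residuals(ols)^2) / nrow(data))
  scale_y <- max(sd(data$value), 1e-8)
  if (ols_sd < 1e-8 * scale_y) {
    b <- coef(ols)
    co <- tibble::tibble(term = names(b), estimate = unname(b),
                         se = 0, conf_low = unname(b), conf_high = unname(b),
                         p_value = NA_real_)
    return(structure(
      list(coefficients = co, sigma_b = 0, sigma_e = 0,
           loglik = as.numeric(logLik(ols)),
           n_obs = nrow(data), n_subjects = length(nv),
           converged = TRUE, singular = TRUE, method = "ols_exact",
           reference = "0", horizon_yrs = horizon_yrs, fit = ols,
           include_main_effects = include_main_effects),
      class = "zs_lme"))
  }

  warn_msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(form, data = data, REML = reml),
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  conv_ok <- length(warn_msgs) == 0 &&
    (is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code == 0)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zcrit <- qnorm(0.975)
  co <- tibble::tibble(
    term = names(b), estimate = unname(b), se = unname(se),
    conf_low = unname(b - zcrit * se), conf_high = unname(b + zcrit * se),
    p_value = 2 * pnorm(-abs(unname(b) / unname(se)))
  )
  vc <- lme4::VarCorr(fit)
  structure(
    list(coefficients = co,
         sigma_b = attr(vc$subject_id, "stddev")[[1]],
         sigma_e = stats::sigma(fit),
         loglik = as.numeric(logLik(fit)),
         n_obs = stats::nobs(fit),
         n_subjects = lme4::ngrps(fit)[["subject_id"]],
         converged = conv_ok, singular = singular, method = "lmer",
         reference = "0", horizon_yrs = horizon_yrs, fit = fit,
         include_main_effects = include_main_effects),
    class = "zs_lme"
  )
}

#' @export
print.zs_lme <- function(x, ...) {
  cat("<zs_lme> random-intercept model (", x$method, "), ", x$n_subjects,
      " subjects / ", x$n_obs, " observations\n", sep = "")
  cat("sigma_b =", format(x$sigma_b, digits = 4),
      " sigma_e =", format(x$sigma_e, digits = 4),
      " logLik =", format(x$loglik, digits = 8), "\n")
  if (!x$converged) cat("NOTE: fit flagged as not converged\n")
  if (x$singular) cat("NOTE: boundary (singular) fit\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' Annualized decline per subtype from a fitted mixed model
#'
#' Combines the reference time slope with each subtype-by-time interaction
#' into per-subtype annualized slopes, with delta-method (here: exact linear
#' combination) standard errors and Wald 95% CIs.
#'
#' @param fit A converged [fit_decline_lme()].
#' @return Tibble with `subtype`, `slope` (score units/yr), `se`,
#'   `conf_low`, `conf_high`, and the interaction column `vs_reference`.
#' @export
decline_summary <- function(fit) {
  stopifnot(inherits(fit, "zs_lme"))
  assert_that(isTRUE(fit$converged), "fit did not converge")
  co <- fit$coefficients
  V <- if (fit$method == "ols_exact") {
    m <- matrix(0, nrow(co), nrow(co), dimnames = list(co$term, co$term))
    m
  } else {
    as.matrix(vcov(fit$fit))
  }
  t_idx <- match("time", co$term)
  assert_that(!is.na(t_idx), "model has no time term")
  int_terms <- grep("^subtype.+:time$", co$term, value = TRUE)
  subtypes <- sub(":time$", "", sub("^subtype", "", int_terms))
  zcrit <- qnorm(0.975)
  ref <- tibble::tibble(subtype = fit$reference,
                        slope = co$estimate[t_idx], se = co$se[t_idx],
                        vs_reference = 0)
  others <- purrr::map_dfr(seq_along(int_terms), function(i) {
    j <- match(int_terms[i], co$term)
    slope <- co$estimate[t_idx] + co$estimate[j]
    v <- V["time", "time"] + V[int_terms[i], int_terms[i]] +
      2 * V["time", int_terms[i]]
    tibble::tibble(subtype = subtypes[i], slope = slope, se = sqrt(max(v, 0)),
                   vs_reference = co$estimate[j])
  })
  out <- dplyr::bind_rows(ref, others)
  out$conf_low <- out$slope - zcrit * out$se
  out$conf_high <- out$slope + zcrit * out$se
  out[, c("subtype", "slope", "se", "conf_low", "conf_high", "vs_reference")]
}
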