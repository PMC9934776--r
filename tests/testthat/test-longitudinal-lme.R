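sim_longitudinal <- function(n_targets, delta, sigma_b, sigma_e, seed,
                             dropout = 0, gamma = c(0, -0.5, 0.2)) {
  lon <- list(visits = 0:4, dropout = dropout,
              scores = list(s = list(beta0 = 3.2, beta_age = -0.05,
                                     gamma = gamma, delta = delta,
                                     sigma_b = sigma_b, sigma_e = sigma_e)))
  cfg <- cohort_config(n_controls = 20, n_targets = n_targets,
                       roi_names = paste0("R", 1:3),
                       true_sequences = list(stair(1:3), stair(3:1)),
                       subtype_fractions = c(0.5, 0.5), stage0_mass = 0.4,
                       longitudinal = lon, seed = seed)
  co <- simulate_cohort(cfg)
  simulate_longitudinal(co, cfg)
}

test_that("noise-free trajectories are recovered exactly", {
  lon <- sim_longitudinal(80, delta = c(-0.05, -0.23, -0.24),
                          sigma_b = 0, sigma_e = 0, seed = 51)
  f <- fit_decline_lme(lon, score = "s")
  expect_identical(f$method, "ols_exact")
  ct <- f$coefficients
  expect_equal(ct$estimate[ct$term == "time"], -0.05, tolerance = 1e-8)
  expect_equal(ct$estimate[ct$term == "subtype1:time"], -0.18,
               tolerance = 1e-8)
  expect_equal(ct$estimate[ct$term == "subtype2:time"], -0.19,
               tolerance = 1e-8)
  expect_equal(ct$estimate[ct$term == "baseline_age"], -0.05,
               tolerance = 1e-8)

  d <- decline_summary(f)
  # reference slope plus interaction gives each subtype's slope exactly
  expect_equal(d$slope[d$subtype == "1"], -0.23, tolerance = 1e-8)
  expect_equal(d$slope[d$subtype == "2"], -0.24, tolerance = 1e-8)
  expect_equal(d$vs_reference[d$subtype == "2"], -0.19, tolerance = 1e-8)
})

test_that("zero interactions give equal subtype slopes", {
  lon <- sim_longitudinal(60, delta = c(-0.1, -0.1, -0.1),
                          sigma_b = 0, sigma_e = 0, seed = 52)
  d <- decline_summary(fit_decline_lme(lon, score = "s"))
  expect_equal(d$slope, rep(-0.1, 3), tolerance = 1e-8)
})

test_that("a worsening-score interaction adds to the reference slope", {
  # +0.09/yr against a 0.01/yr reference, the pattern reported for
  # functional-rating scores
  lon <- sim_longitudinal(60, delta = c(0.01, 0.10, 0.01),
                          sigma_b = 0, sigma_e = 0, seed = 53,
                          gamma = c(0, 0.1, 0))
  d <- decline_summary(fit_decline_lme(lon, score = "s"))
  expect_equal(d$vs_reference[d$subtype == "1"], 0.09, tolerance = 1e-8)
  expect_equal(d$slope[d$subtype == "1"], 0.01 + 0.09, tolerance = 1e-8)
})

test_that("fixed effects match closed-form GLS at the fitted variances", {
  lon <- sim_longitudinal(120, delta = c(0, -0.23, -0.24),
                          sigma_b = 1.5, sigma_e = 1, seed = 54)
  f <- fit_decline_lme(lon, score = "s")
  expect_identical(f$method, "lmer")
  expect_true(f$converged)

  lon$subtype <- stats::relevel(factor(lon$subtype), ref = "0")
  X <- stats::model.matrix(~ baseline_age + subtype + time + subtype:time,
                           data = lon)
  beta <- oracle_gls_cs(X, lon$value, lon$subject_id, f$sigma_b, f$sigma_e)
  got <- f$coefficients$estimate
  names(got) <- f$coefficients$term
  expect_equal(unname(got[colnames(X)[-1]]), unname(beta[-1]),
               tolerance = 1e-6)
  expect_equal(unname(got["(Intercept)"]), unname(beta[1]), tolerance = 1e-6)
})

test_that("model log-likelihood dominates the fixed-effects-only submodel", {
  lon <- sim_longitudinal(100, delta = c(0, -0.2, -0.1),
                          sigma_b = 1.5, sigma_e = 1, seed = 55)
  f <- fit_decline_lme(lon, score = "s")
  lon$subtype <- stats::relevel(factor(lon$subtype), ref = "0")
  ols <- lm(value ~ baseline_age + subtype + time + subtype:time, data = lon)
  expect_gte(f$loglik, as.numeric(logLik(ols)) - 1e-6)
})

test_that("observation window, ordering and diagnostics behave", {
  lon <- sim_longitudinal(60, delta = c(0, -0.2, -0.1),
                          sigma_b = 1, sigma_e = 0.8, seed = 56)
  extra <- dplyr::mutate(lon[lon$time == 4, ], time = 6)
  f <- fit_decline_lme(dplyr::bind_rows(lon, extra), score = "s",
                       horizon_yrs = 4)
  expect_identical(f$n_obs, nrow(lon)) # beyond-horizon visits dropped

  perm <- withr::with_seed(57, sample(nrow(lon)))
  f2 <- fit_decline_lme(lon[perm, ], score = "s")
  expect_equal(f$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)

  g <- glance(f)
  expect_true(g$n_obs >= g$n_subjects)
  expect_true(all(f$coefficients$conf_low <= f$coefficients$estimate &
                    f$coefficients$estimate <= f$coefficients$conf_high))

  expect_error(fit_decline_lme(lon[lon$time == 0, ], score = "s"),
               "10 subjects")
})

test_that("confidence intervals tighten as residual noise shrinks", {
  widths <- vapply(c(2.4, 1.2, 0.4), function(se) {
    lon <- sim_longitudinal(150, delta = c(0, -0.23, -0.24),
                            sigma_b = 1, sigma_e = se, seed = 58)
    f <- fit_decline_lme(lon, score = "s")
    ct <- f$coefficients
    ct$conf_high[ct$term == "subtype1:time"] -
      ct$conf_low[ct$term == "subtype1:time"]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
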