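test_that("cohort simulation is reproducible and honors degenerate settings", {
  rois <- paste0("R", 1:3)
  cfg <- cohort_config(n_controls = 40, n_targets = 60, roi_names = rois,
                       true_sequences = list(stair(1:3)),
                       subtype_fractions = 1, stage0_mass = 0.3,
                       longitudinal = FALSE, seed = 9)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))

  cfg0 <- cohort_config(n_controls = 20, n_targets = 50, roi_names = rois,
                        true_sequences = list(stair(1:3)),
                        subtype_fractions = 1, stage0_mass = 1,
                        longitudinal = FALSE, seed = 2)
  co0 <- simulate_cohort(cfg0)
  expect_true(all(dplyr::filter(co0, group == "target")$true_stage == 0))
})

test_that("latent subtype counts follow the configured fractions", {
  fr <- c(0.5, 0.25, 0.25)
  seqs <- list(stair(1:3), stair(3:1), stair(c(2, 1, 3)))
  cfg <- cohort_config(n_controls = 20, n_targets = 2000,
                       roi_names = paste0("R", 1:3), true_sequences = seqs,
                       subtype_fractions = fr, stage0_mass = 0,
                       longitudinal = FALSE, seed = 4)
  co <- simulate_cohort(cfg)
  counts <- table(factor(dplyr::filter(co, group == "target")$true_subtype,
                         levels = 1:3))
  for (c in 1:3) {
    expected <- 2000 * fr[c]
    band <- 3 * sqrt(2000 * fr[c] * (1 - fr[c]))
    expect_lt(abs(counts[[c]] - expected), band)
  }
})

test_that("ground-truth stage distribution matches the configured one", {
  E <- 6
  probs <- c(0.4, rep(0.6 / E, E))
  cfg <- cohort_config(n_controls = 20, n_targets = 5000,
                       roi_names = paste0("R", 1:3),
                       true_sequences = list(stair(1:3)),
                       subtype_fractions = 1, stage_distribution = probs,
                       longitudinal = FALSE, seed = 8)
  co <- simulate_cohort(cfg)
  stages <- factor(dplyr::filter(co, group == "target")$true_stage,
                   levels = 0:E)
  gof <- suppressWarnings(stats::chisq.test(table(stages), p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("control volumes embed the generating covariate model", {
  rois <- paste0("R", 1:4)
  cfg <- cohort_config(n_controls = 400, n_targets = 10, roi_names = rois,
                       true_sequences = list(stair(1:4)),
                       subtype_fractions = 1, longitudinal = FALSE, seed = 3)
  co <- simulate_cohort(cfg)
  fit <- fit_control_glm(co, rois = rois)
  ctrl <- dplyr::filter(co, group == "control")
  X <- cbind(1, ctrl$age, as.numeric(ctrl$sex == "F"), ctrl$education,
             ctrl$icv)
  XtXinv <- solve(crossprod(X))
  cm <- cfg$covariate_model
  zs <- unlist(lapply(seq_along(rois), function(j) {
    est <- unlist(fit$coefficients[j, c("intercept", "beta_age", "beta_sex",
                                        "beta_educ", "beta_icv")])
    truth <- unlist(cm[j, c("intercept", "beta_age", "beta_sex",
                            "beta_educ", "beta_icv")])
    se <- fit$coefficients$resid_sd[j] * sqrt(diag(XtXinv))
    (est - truth) / se
  }))
  # 20 simultaneous coefficients: marginally each sits within 3 SE, so allow
  # one mild exceedance jointly but nothing beyond 4 SE
  expect_lt(max(abs(zs)), 4)
  expect_gte(mean(abs(zs) < 3), 0.95)
})

test_that("longitudinal generator follows the linear mixed model", {
  rois <- paste0("R", 1:3)
  base_scores <- function(delta, sigma_b, sigma_e) {
    list(visits = 0:4, dropout = 0,
         scores = list(s = list(beta0 = 1, beta_age = 0.1,
                                gamma = c(0, 0.5), delta = delta,
                                sigma_b = sigma_b, sigma_e = sigma_e)))
  }
  # no noise, no slopes: constant within subject
  cfg <- cohort_config(n_controls = 20, n_targets = 30, roi_names = rois,
                       true_sequences = list(stair(1:3)),
                       subtype_fractions = 1, stage0_mass = 0.5,
                       longitudinal = base_scores(c(0, 0), 0, 0), seed = 5)
  co <- simulate_cohort(cfg)
  lon <- simulate_longitudinal(co, cfg)
  spread <- dplyr::summarise(dplyr::group_by(lon, subject_id),
                             d = diff(range(value)))
  expect_true(all(spread$d < 1e-12))
  expect_identical(nrow(lon), 30L * 5L) # dropout 0: 5 visits per subject

  # published slope as ground truth: -0.24/yr over 4 years is -0.96
  cfg2 <- cohort_config(n_controls = 20, n_targets = 1, roi_names = rois,
                        true_sequences = list(stair(1:3)),
                        subtype_fractions = 1, stage0_mass = 0,
                        longitudinal = base_scores(c(0, -0.24), 1.5, 0),
                        seed = 6)
  co2 <- simulate_cohort(cfg2)
  lon2 <- simulate_longitudinal(co2, cfg2)
  expect_equal(lon2$value[lon2$time == 4] - lon2$value[lon2$time == 0],
               -0.96, tolerance = 1e-12)

  expect_error(
    simulate_longitudinal(dplyr::select(co2, -true_subtype), cfg2),
    "subtype labels"
  )
})

test_that("between-subject intercept variance matches sigma_b^2", {
  rois <- paste0("R", 1:3)
  sigma_b <- 1.5
  sigma_e <- 0.8
  lon_cfg <- list(visits = 0:4, dropout = 0,
                  scores = list(s = list(beta0 = 2, beta_age = 0,
                                         gamma = c(0, 0), delta = c(0, 0),
                                         sigma_b = sigma_b,
                                         sigma_e = sigma_e)))
  cfg <- cohort_config(n_controls = 20, n_targets = 1000, roi_names = rois,
                       true_sequences = list(stair(1:3)),
                       subtype_fractions = 1, stage0_mass = 0.5,
                       longitudinal = lon_cfg, seed = 7)
  co <- simulate_cohort(cfg)
  lon <- simulate_longitudinal(co, cfg)
  means <- dplyr::summarise(dplyr::group_by(lon, subject_id),
                            m = mean(value))$m
  est <- stats::var(means) - sigma_e^2 / 5 # subject means carry sigma_e^2/V
  expect_lt(abs(est - sigma_b^2), 0.2 * sigma_b^2)
})

test_that("invalid configurations are rejected", {
  rois <- paste0("R", 1:3)
  expect_error(cohort_config(roi_names = rois,
                             true_sequences = list(stair(1:3)),
                             subtype_fractions = c(0.5, 0.6)),
               "fraction")
  bad_seq <- c(2L, 1L, 3L, 4L, 5L, 6L) # z=2 before z=1 for biomarker 1
  expect_error(cohort_config(roi_names = rois,
                             true_sequences = list(bad_seq),
                             subtype_fractions = 1),
               "valid event ordering")
})
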