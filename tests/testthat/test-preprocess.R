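make_exact_controls <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("C%03d", seq_len(n)),
      group = "control",
      age = runif(n, 60, 85),
      sex = ifelse(runif(n) < 0.5, "F", "M"),
      education = round(runif(n, 10, 20)),
      icv = runif(n, 1.2e6, 1.7e6)
    )
  })
}

test_that("noise-free controls are interpolated exactly", {
  ctrl <- make_exact_controls()
  b <- c(5000, -12, -80, 6, 0.002)
  ctrl$hippo <- b[1] + b[2] * ctrl$age + b[3] * (ctrl$sex == "F") +
    b[4] * ctrl$education + b[5] * ctrl$icv
  fit <- fit_control_glm(ctrl, rois = "hippo")
  est <- unlist(fit$coefficients[1, c("intercept", "beta_age", "beta_sex",
                                      "beta_educ", "beta_icv")])
  expect_equal(unname(est), b, tolerance = 1e-10)
})

test_that("noisy controls recover coefficients within 3 standard errors", {
  ctrl <- make_exact_controls(n = 200, seed = 2)
  b <- c(4000, -10, -60, 5, 0.0015)
  withr::with_seed(3, {
    ctrl$roi1 <- b[1] + b[2] * ctrl$age + b[3] * (ctrl$sex == "F") +
      b[4] * ctrl$education + b[5] * ctrl$icv + rnorm(200, sd = 150)
  })
  fit <- fit_control_glm(ctrl, rois = "roi1")
  X <- cbind(1, ctrl$age, as.numeric(ctrl$sex == "F"), ctrl$education,
             ctrl$icv)
  se <- fit$coefficients$resid_sd[1] * sqrt(diag(solve(crossprod(X))))
  est <- unlist(fit$coefficients[1, c("intercept", "beta_age", "beta_sex",
                                      "beta_educ", "beta_icv")])
  expect_true(all(abs(est - b) < 3 * se))
  # residual sd uses the n - 5 denominator
  res <- ctrl$roi1 - X %*% coef(lm(ctrl$roi1 ~ X - 1))
  expect_equal(fit$coefficients$resid_sd[1], sqrt(sum(res^2) / (200 - 5)),
               tolerance = 1e-12)
})

test_that("preconditions and degeneracies raise informative errors", {
  ctrl <- make_exact_controls(n = 4)
  ctrl$roi1 <- rnorm(4)
  expect_error(fit_control_glm(ctrl, rois = "roi1"), "at least 10 controls")

  ctrl2 <- make_exact_controls(n = 30)
  ctrl2$education <- 16 # constant covariate
  ctrl2$roi1 <- rnorm(30)
  expect_error(fit_control_glm(ctrl2, rois = "roi1"), "education")
})

test_that("z-scores follow the sign-flipped standardization", {
  ctrl <- make_exact_controls(n = 50, seed = 4)
  withr::with_seed(5, {
    ctrl$roi1 <- 3000 - 8 * ctrl$age + 0.001 * ctrl$icv + rnorm(50, sd = 40)
    ctrl$roi2 <- 7000 - 15 * ctrl$age + 0.002 * ctrl$icv + rnorm(50, sd = 90)
  })
  fit <- fit_control_glm(ctrl, rois = c("roi1", "roi2"))
  z_ctrl <- compute_zscores(ctrl, fit)
  # OLS residuals average zero in-sample
  expect_lt(max(abs(colMeans(z_ctrl[, c("roi1", "roi2")]))), 1e-10)

  # a subject exactly on the fitted plane, and one 2 residual-sds below it
  cf <- fit$coefficients
  subj <- tibble::tibble(subject_id = c("T1", "T2"), group = "target",
                         age = 70, sex = "F", education = 16, icv = 1.4e6)
  pred <- cf$intercept + cf$beta_age * 70 + cf$beta_sex * 1 +
    cf$beta_educ * 16 + cf$beta_icv * 1.4e6
  subj$roi1 <- c(pred[1], pred[1] - 2 * cf$resid_sd[1])
  subj$roi2 <- c(pred[2], pred[2] - 2 * cf$resid_sd[2])
  z <- compute_zscores(subj, fit)
  expect_equal(unlist(z[1, c("roi1", "roi2")]), c(roi1 = 0, roi2 = 0),
               tolerance = 1e-10)
  expect_equal(unlist(z[2, c("roi1", "roi2")]), c(roi1 = 2, roi2 = 2),
               tolerance = 1e-10)

  # z-scoring then inverting reproduces the input volumes
  inv1 <- pred[1] - z$roi1 * cf$resid_sd[1]
  expect_equal(inv1, subj$roi1, tolerance = 1e-9 * abs(pred[1]))

  # subjects with a missing ROI are excluded and reported
  subj2 <- subj
  subj2$roi2[2] <- NA
  z2 <- compute_zscores(subj2, fit)
  expect_identical(nrow(z2), 1L)
  expect_identical(attr(z2, "excluded"), "T2")

  expect_error(compute_zscores(dplyr::select(subj, -roi2), fit),
               "ROI mismatch")
})

test_that("control-sd scaling differs from residual scaling by a constant", {
  ctrl <- make_exact_controls(n = 60, seed = 6)
  withr::with_seed(7, ctrl$roi1 <- 2000 - 5 * ctrl$age + rnorm(60, sd = 30))
  fit <- fit_control_glm(ctrl, rois = "roi1")
  z_res <- compute_zscores(ctrl, fit, scale = "residual")
  z_ctl <- compute_zscores(ctrl, fit, scale = "control_sd")
  ratio <- z_res$roi1 / z_ctl$roi1
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("eligibility filter applies inclusive bounds and amyloid rule", {
  co <- tibble::tibble(
    subject_id = paste0("S", 1:6),
    group = "target",
    mmse = c(24, 25, 30, 28, 27, 29),
    cdr_global = c(0, 0, 0, 0.5, 0, 0),
    lmdr = c(10, 10, 18, 12, 5, 12),
    suvr = c(1.3, 1.15, 1.10, 1.4, 1.3, NA),
    csf_ab42 = c(NA, NA, NA, NA, NA, c(977))
  )
  out <- apply_eligibility(co, eligibility_rules(), exempt_controls = FALSE)
  log <- attr(out, "exclusion_log")
  # S1: MMSE 24 out; S3: SUVr below 1.15 and no CSF; S4: CDR 0.5;
  # S5: LMDR 5; S6: CSF exactly at the cut-off is NOT positive (strict below)
  expect_identical(out$subject_id, "S2") # SUVr exactly 1.15 is retained
  expect_identical(log$n_excluded[log$rule == "mmse"], 1L)
  expect_identical(log$n_excluded[log$rule == "cdr_global"], 1L)
  expect_identical(log$n_excluded[log$rule == "lmdr"], 1L)
  expect_identical(log$n_excluded[log$rule == "amyloid"], 2L)

  # strictly-below CSF passes
  co$csf_ab42[6] <- 976.9
  co$mmse[6] <- 29
  out2 <- apply_eligibility(co, eligibility_rules(), exempt_controls = FALSE)
  expect_true("S6" %in% out2$subject_id)

  # empty rule set is the identity; the filter is idempotent
  expect_equal(apply_eligibility(co, list()), co, ignore_attr = TRUE)
  once <- apply_eligibility(co, eligibility_rules(), exempt_controls = FALSE)
  twice <- apply_eligibility(once, eligibility_rules(),
                             exempt_controls = FALSE)
  expect_equal(once, twice, ignore_attr = TRUE)

  expect_error(apply_eligibility(co, list(nonexistent = c(0, 1))),
               "absent column")
})
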