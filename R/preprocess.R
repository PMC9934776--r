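#' Fit the control general linear model of regional volumes
#'
#' Ordinary least squares per ROI, on controls only, of volume on age,
#' sex (F = 1), education years and intracranial volume. The residual
#' standard deviation uses denominator `n - 5` (intercept plus four slopes).
#' This GLM defines "healthy/normal" volume trends; departures from it become
#' abnormality z-scores via [compute_zscores()].
#'
#' @param cohort Cohort tibble (needs `group`, `age`, `sex`, `education`,
#'   `icv` and one column per ROI).
#' @param rois ROI column names. Default: every [default_rois()] name present.
#' @return A `zs_control_glm`: tibble of per-ROI coefficients and residual
#'   sd (`resid_sd`), plus the sd of control residuals computed with an
#'   `n - 1` denominator (`control_sd`), and `n_controls`.
#' @export
fit_control_glm <- function(cohort, rois = intersect(default_rois(), names(cohort))) {
  assert_that(length(rois) >= 1, "no ROI columns found in cohort")
  ctrl <- dplyr::filter(cohort, .data$group == "control")
  need <- c("age", "sex", "education", "icv", rois)
  missing_cols <- setdiff(need, names(ctrl))
  assert_that(length(missing_cols) == 0,
              paste("cohort lacks columns:", paste(missing_cols, collapse = ", ")))
  ctrl <- ctrl[complete.cases(ctrl[, need]), ]
  assert_that(nrow(ctrl) >= 10,
              "at least 10 controls with complete covariates and volumes are required")
  X <- cbind(1, ctrl$age, as.numeric(ctrl$sex == "F"), ctrl$education, ctrl$icv)
  colnames(X) <- c("intercept", "age", "sex", "education", "icv")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("rank-deficient control design; constant or collinear covariate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- purrr::map_dfr(rois, function(r) {
    fit <- lm(ctrl[[r]] ~ X - 1)
    b <- unname(coef(fit))
    res <- stats::residuals(fit)
    tibble::tibble(
      roi = r, intercept = b[1], beta_age = b[2], beta_sex = b[3],
      beta_educ = b[4], beta_icv = b[5],
      resid_sd = sqrt(sum(res^2) / (nrow(ctrl) - ncol(X))),
      control_sd = sd(res)
    )
  })
  structure(list(coefficients = coefs, n_controls = nrow(ctrl)),
            class = "zs_control_glm")
}

#' @export
print.zs_control_glm <- function(x, ...) {
  cat("<zs_control_glm> fitted on", x$n_controls, "controls,",
      nrow(x$coefficients), "ROIs\n")
  print(x$coefficients, ...)
  invisible(x)
}

# Predicted volumes for arbitrary subjects under a control GLM.
glm_predict <- function(cohort, glm) {
  cf <- glm$coefficients
  sex_f <- as.numeric(cohort$sex == "F")
  pred <- vapply(seq_len(nrow(cf)), function(j) {
    cf$intercept[j] + cf$beta_age[j] * cohort$age + cf$beta_sex[j] * sex_f +
      cf$beta_educ[j] * cohort$education + cf$beta_icv[j] * cohort$icv
  }, numeric(nrow(cohort)))
  pred <- matrix(pred, nrow = nrow(cohort), ncol = nrow(cf))
  colnames(pred) <- cf$roi
  pred
}

#' Covariate-adjust volumes and convert to abnormality z-scores
#'
#' For each subject and ROI, `z = (predicted - observed) / scale`, where the
#' prediction comes from the control GLM. The sign is flipped so that volume
#' loss (atrophy) yields a positive z, matching the event thresholds z = 1
#' and z = 2. Subjects missing any ROI or covariate are excluded and reported
#' via the `"excluded"` attribute (complete-data analysis).
#'
#' @param cohort Cohort tibble.
#' @param glm A [fit_control_glm()].
#' @param scale Which denominator standardizes the adjusted volumes:
#'   `"residual"` (GLM residual sd, default) or `"control_sd"` (sd of the
#'   controls' adjusted volumes). The two differ by a constant factor per ROI.
#' @return Tibble with `subject_id`, `group`, and one z column per ROI;
#'   attribute `"excluded"` holds the ids of dropped subjects.
#' @export
compute_zscores <- function(cohort, glm, scale = c("residual", "control_sd")) {
  scale <- match.arg(scale)
  cf <- glm$coefficients
  rois <- cf$roi
  missing_cols <- setdiff(rois, names(cohort))
  assert_that(length(missing_cols) == 0,
              paste("ROI mismatch between cohort and GLM:",
                    paste(missing_cols, collapse = ", ")))
  need <- c("age", "sex", "education", "icv", rois)
  ok <- complete.cases(cohort[, need])
  excluded <- cohort$subject_id[!ok]
  dat <- cohort[ok, ]
  pred <- glm_predict(dat, glm)
  obs <- as.matrix(dat[, rois])
  denom <- if (scale == "residual") cf$resid_sd else cf$control_sd
  z <- (pred - obs) / matrix(denom, nrow(dat), length(rois), byrow = TRUE)
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = dat$subject_id, group = dat$group),
    tibble::as_tibble(z)
  )
  attr(out, "excluded") <- excluded
  out
}

#' Default preclinical-trial eligibility rules
#'
#' Screening bounds used for cognitively unimpaired amyloid-positive
#' enrolment: MMSE 25-30, CDR global 0, Logical Memory Delayed Recall 6-18,
#' and amyloid positivity defined as PET SUVr >= 1.15 (inclusive) or CSF
#' Abeta42 strictly below 977 pg/mL, whichever measurement is available.
#'
#' @return Named list of rules for [apply_eligibility()]: numeric
#'   `c(lower, upper)` bounds keyed by column name, plus an `amyloid`
#'   element with `suvr_min` and `csf_max`.
#' @export
eligibility_rules <- function() {
  list(
    mmse = c(25, 30),
    cdr_global = c(0, 0),
    lmdr = c(6, 18),
    amyloid = list(suvr_min = 1.15, csf_max = 977)
  )
}

#' Filter a cohort by eligibility rules
#'
#' Retains rows satisfying every rule (bounds are inclusive; missing values
#' fail the rule they are missing for). The amyloid rule passes if SUVr is
#' at or above `suvr_min` or CSF Abeta42 is strictly below `csf_max`, using
#' whichever variable is observed. Controls are exempt from the amyloid rule
#' (they are selected amyloid-negative).
#'
#' @param cohort Cohort tibble.
#' @param rules As [eligibility_rules()]; an empty list leaves the table
#'   unchanged.
#' @param exempt_controls Apply the amyloid rule to targets only? Default TRUE.
#' @return The filtered tibble; attribute `"exclusion_log"` is a tibble of
#'   per-rule exclusion counts (a row may be counted under several rules).
#' @export
apply_eligibility <- function(cohort, rules = eligibility_rules(),
                              exempt_controls = TRUE) {
  keep <- rep(TRUE, nrow(cohort))
  log <- tibble::tibble(rule = character(), n_excluded = integer())
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (identical(nm, "amyloid")) {
      has_suvr <- "suvr" %in% names(cohort)
      has_csf <- "csf_ab42" %in% names(cohort)
      assert_that(has_suvr || has_csf,
                  "amyloid rule requires a 'suvr' or 'csf_ab42' column")
      pass <- rep(FALSE, nrow(cohort))
      if (has_suvr) pass <- pass | (!is.na(cohort$suvr) & cohort$suvr >= r$suvr_min)
      if (has_csf) pass <- pass | (!is.na(cohort$csf_ab42) & cohort$csf_ab42 < r$csf_max)
      if (exempt_controls && "group" %in% names(cohort)) {
        pass <- pass | cohort$group == "control"
      }
    } else {
      assert_that(nm %in% names(cohort),
                  paste0("eligibility rule references absent column: ", nm))
      v <- cohort[[nm]]
      pass <- !is.na(v) & v >= r[1] & v <= r[2]
    }
    log <- dplyr::bind_rows(log, tibble::tibble(rule = nm,
                                                n_excluded = sum(keep & !pass)))
    keep <- keep & pass
  }
  out <- cohort[keep, ]
  attr(out, "exclusion_log") <- log
  out
}
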