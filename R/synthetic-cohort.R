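#' Default regions of interest
#'
#' Thirteen bilateral regions spanning cortical lobes and subcortical
#' structures, ordered cortical-to-subcortical (the convention used when
#' plotting positional variance diagrams).
#'
#' @return Character vector of 13 ROI names.
#' @export
default_rois <- function() {
  c("frontal", "parietal", "temporal", "occipital", "cingulate", "insula",
    "entorhinal", "hippocampus", "amygdala", "thalamus", "caudate",
    "putamen", "pallidum")
}

# Plausible bilateral-average volumes (mm^3) used to scale the default
# covariate model.
default_base_volumes <- function(rois) {
  base <- c(frontal = 85000, parietal = 60000, temporal = 70000,
            occipital = 40000, cingulate = 25000, insula = 15000,
            entorhinal = 1900, hippocampus = 3500, amygdala = 1600,
            thalamus = 7000, caudate = 3600, putamen = 4500, pallidum = 1500)
  out <- base[rois]
  out[is.na(out)] <- 20000
  names(out) <- rois
  out
}

#' Default covariate model for synthetic volumes
#'
#' Linear trends of regional volume in age (yrs), sex (F = 1), education
#' (yrs) and intracranial volume (mm^3), with Gaussian residuals; one row
#' per ROI. Effects are proportional to each region's typical volume:
#' -0.3%/yr of age, -2% for female sex, +0.1%/yr of education, and an ICV
#' slope of half the region-to-ICV ratio; residual sd 6% of typical volume.
#'
#' @param rois Character vector of ROI names.
#' @return Tibble with columns `roi`, `intercept`, `beta_age`, `beta_sex`,
#'   `beta_educ`, `beta_icv`, `resid_sd`.
#' @export
default_covariate_model <- function(rois = default_rois()) {
  base <- default_base_volumes(rois)
  beta_age <- -0.003 * base
  beta_sex <- -0.02 * base
  beta_educ <- 0.001 * base
  beta_icv <- 0.5 * base / 1.45e6
  intercept <- base - (beta_age * 71 + beta_sex * 0.6 + beta_educ * 16.6 +
                         beta_icv * 1.45e6)
  tibble::tibble(roi = rois, intercept = unname(intercept),
                 beta_age = unname(beta_age), beta_sex = unname(beta_sex),
                 beta_educ = unname(beta_educ), beta_icv = unname(beta_icv),
                 resid_sd = unname(0.06 * base))
}

# Three default ground-truth orderings over the ROI grid, loosely emulating
# medial-temporal-first, cortical-first and subcortical-first atrophy.
default_true_sequences <- function(events) {
  ev <- events$events
  order_by_roi <- function(roi_order) {
    ranks <- match(ev$roi, roi_order)
    # all z=1 events in roi_order, then all z=2 events in roi_order
    ev$event[order(ev$level, ranks)]
  }
  rois <- events$biomarkers
  n <- length(rois)
  list(
    order_by_roi(rois[order(seq_len(n) * -1)]),  # subcortical-to-cortical
    order_by_roi(rois),                          # cortical-to-subcortical
    order_by_roi(rois[((seq_len(n) + floor(n / 2) - 1) %% n) + 1])
  )
}

#' Configuration of a synthetic cohort
#'
#' Defines the generative model used by [simulate_cohort()] and
#' [simulate_longitudinal()]: control volumes follow linear covariate trends
#' plus Gaussian noise; amyloid-positive targets are drawn from latent
#' atrophy subtypes, each an event ordering over z = 1 / z = 2 threshold
#' crossings, with abnormality z-scores drawn around the subtype trajectory
#' and mapped back to volumes by inverting the covariate model. Defaults
#' emulate a preclinical (cognitively unimpaired, amyloid-positive) cohort:
#' 407 controls, 1240 targets, 13 ROIs, three equal atrophy subtypes and a
#' 0.55 probability mass at stage zero.
#'
#' @param n_controls,n_targets Number of amyloid-negative controls / amyloid-
#'   positive target subjects.
#' @param roi_names ROI names (defines the biomarker set).
#' @param thresholds,z_max Event thresholds and final-stage z (see
#'   [event_set()]).
#' @param true_sequences List of ground-truth event orderings, one per latent
#'   subtype. Default: three stylized orderings over the ROI grid.
#' @param subtype_fractions Simplex weights over the latent subtypes
#'   (conditional on not being at stage zero).
#' @param stage0_mass Probability that a target sits at stage 0 (sub-threshold,
#'   "subtype zero"). Default 0.55.
#' @param stage_distribution Optional probability vector over stages `0..E`;
#'   overrides `stage0_mass` + uniform when supplied.
#' @param covariate_model Tibble as [default_covariate_model()].
#' @param z_noise_sd Standard deviation of target subjects' abnormality
#'   z-scores around their expected trajectory, in control-sd units. Default
#'   1. Controls always have unit z noise: they define the reference scale
#'   that control-based standardization recovers.
#' @param longitudinal Named list: `visits` (yrs), `dropout` (per-visit
#'   probability), and `scores`, a named list per score with `beta0`,
#'   `beta_age`, `gamma` (subtype main effects, reference first), `delta`
#'   (subtype slopes /yr, reference first), `sigma_b`, `sigma_e`. `NULL`
#'   (default) uses [default_longitudinal_config()] sized to the number of
#'   subtypes; `FALSE` disables longitudinal generation.
#' @param include_eligibility Generate screening variables (MMSE, CDR global,
#'   LMDR, SUVr, CSF Ab42)? Default TRUE.
#' @param seed Integer seed; one seed drives all sub-generators via
#'   independent child streams.
#' @return A validated `zs_cohort_config` list, with the implied
#'   [event_set()] under `$events` and full stage distribution under
#'   `$stage_probs`.
#' @export
cohort_config <- function(n_controls = 407,
                          n_targets = 1240,
                          roi_names = default_rois(),
                          thresholds = c(1, 2),
                          z_max = 5,
                          true_sequences = NULL,
                          subtype_fractions = NULL,
                          stage0_mass = 0.55,
                          stage_distribution = NULL,
                          covariate_model = default_covariate_model(roi_names),
                          z_noise_sd = 1,
                          longitudinal = NULL,
                          include_eligibility = TRUE,
                          seed = 1L) {
  events <- event_set(roi_names, thresholds = thresholds, z_max = z_max)
  if (is.null(true_sequences)) true_sequences <- default_true_sequences(events)
  C <- length(true_sequences)
  if (is.null(subtype_fractions)) subtype_fractions <- rep(1 / C, C)
  assert_that(length(subtype_fractions) == C,
              "one fraction per true sequence is required")
  assert_that(all(subtype_fractions >= 0) &&
                abs(sum(subtype_fractions) - 1) < 1e-12,
              "subtype_fractions must be a simplex summing to 1 (within 1e-12)")
  for (s in true_sequences) {
    assert_that(is_valid_sequence(s, events),
                "every true_sequence must be a valid event ordering")
  }
  if (is.null(stage_distribution)) {
    assert_that(stage0_mass >= 0 && stage0_mass <= 1,
                "stage0_mass must lie in [0, 1]")
    stage_probs <- c(stage0_mass, rep((1 - stage0_mass) / events$E, events$E))
  } else {
    assert_that(length(stage_distribution) == events$E + 1 &&
                  all(stage_distribution >= 0) &&
                  abs(sum(stage_distribution) - 1) < 1e-12,
                "stage_distribution must be a probability vector over stages 0..E")
    stage_probs <- stage_distribution
  }
  cm <- tibble::as_tibble(covariate_model)
  assert_that(setequal(cm$roi, roi_names) && nrow(cm) == length(roi_names),
              "covariate_model must have exactly one row per ROI")
  assert_that(all(cm$resid_sd > 0), "all residual sds must be positive")
  assert_that(z_noise_sd > 0, "z_noise_sd must be positive")
  lon <- longitudinal
  if (is.null(lon)) lon <- default_longitudinal_config(C)
  if (isFALSE(lon)) lon <- NULL
  if (!is.null(lon)) {
    for (nm in names(lon$scores)) {
      sc <- lon$scores[[nm]]
      assert_that(length(sc$gamma) == C + 1 && length(sc$delta) == C + 1,
                  paste0("score '", nm, "' needs gamma/delta of length C+1 ",
                         "(reference subtype zero first)"))
      assert_that(sc$sigma_b >= 0 && sc$sigma_e >= 0,
                  "longitudinal sds must be non-negative")
    }
    assert_that(all(lon$visits >= 0) && lon$visits[1] == 0,
                "visit schedule must start at 0 and be non-negative")
    assert_that(lon$dropout >= 0 && lon$dropout < 1,
                "dropout must be in [0, 1)")
  }
  structure(
    list(n_controls = n_controls, n_targets = n_targets,
         roi_names = roi_names, events = events,
         true_sequences = true_sequences,
         subtype_fractions = subtype_fractions,
         stage_probs = stage_probs,
         covariate_model = cm[match(roi_names, cm$roi), ],
         z_noise_sd = z_noise_sd,
         longitudinal = lon,
         include_eligibility = include_eligibility,
         seed = as.integer(seed)),
    class = "zs_cohort_config"
  )
}

#' Default longitudinal generative parameters
#'
#' Two trial-style outcomes over annual visits to 4 years: a PACC-like
#' cognitive composite (declining in the two cortical-involving subtypes at
#' -0.23 and -0.24 points/yr relative to subtype zero) and a CDR-SB-like
#' score (worsening at +0.09 and +0.07 points/yr). Variance components are
#' sized so that subtype-by-time confidence intervals at a few hundred
#' subjects are comparable to those reported for preclinical cohorts.
#'
#' @param n_subtypes Number of atrophy subtypes (reference subtype zero is
#'   added automatically).
#' @return Named list with `visits`, `dropout`, `scores`.
#' @export
default_longitudinal_config <- function(n_subtypes = 3) {
  pad <- function(x) c(x, rep(0, max(0, n_subtypes + 1 - length(x))))[seq_len(n_subtypes + 1)]
  list(
    visits = 0:4,
    dropout = 0.10,
    scores = list(
      mPACC = list(beta0 = 3.2, beta_age = -0.05,
                   gamma = pad(c(0, -0.6, -1.0, 0.1)),
                   delta = pad(c(0, -0.23, -0.24, 0)),
                   sigma_b = 2.0, sigma_e = 2.8),
      CDRSB = list(beta0 = -0.22, beta_age = 0.004,
                   gamma = pad(c(0, 0.02, 0.01, 0.01)),
                   delta = pad(c(0, 0.09, 0.07, 0)),
                   sigma_b = 0.25, sigma_e = 0.45)
    )
  )
}

draw_covariates <- function(n) {
  tibble::tibble(
    age = round(pmax(rnorm(n, 71.5, 4.8), 55), 1),
    sex = ifelse(runif(n) < 0.59, "F", "M"),
    education = round(pmin(pmax(rnorm(n, 16.6, 2.8), 8), 24)),
    icv = round(rnorm(n, 1.45e6, 1.4e5))
  )
}

predicted_volumes <- function(cov, cm) {
  sex_f <- as.numeric(cov$sex == "F")
  vapply(seq_len(nrow(cm)), function(j) {
    cm$intercept[j] + cm$beta_age[j] * cov$age + cm$beta_sex[j] * sex_f +
      cm$beta_educ[j] * cov$education + cm$beta_icv[j] * cov$icv
  }, numeric(nrow(cov)))
}

#' Simulate a cross-sectional cohort
#'
#' Controls are drawn at stage 0 (z noise only). Each target is assigned a
#' latent subtype and stage from the configured distributions; its
#' abnormality z-scores are drawn as
#' `Normal(expected_trajectory(subtype sequence, stage), z_noise_sd)` and
#' mapped back to volumes by inverting the covariate model
#' (`volume = predicted - z * resid_sd`, so larger z means more atrophy).
#'
#' @param config A [cohort_config()].
#' @return A tibble with `subject_id`, `group` ("control"/"target"),
#'   covariates, one volume column per ROI (mm^3), optional eligibility
#'   variables, and ground-truth `true_subtype` (0 = stage-zero mass) and
#'   `true_stage` for targets.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "zs_cohort_config"))
  with_seed_if(child_seed(config$seed, 1L), {
    events <- config$events
    cm <- config$covariate_model
    nC <- config$n_controls
    nT <- config$n_targets
    n <- nC + nT
    cov <- draw_covariates(n)
    group <- rep(c("control", "target"), c(nC, nT))
    pred <- predicted_volumes(cov, cm)

    # latent subtype and stage for targets
    stage <- rep(NA_integer_, n)
    subtype <- rep(NA_integer_, n)
    t_idx <- which(group == "target")
    stage[t_idx] <- sample(0:events$E, nT, replace = TRUE,
                           prob = config$stage_probs)
    C <- length(config$true_sequences)
    subtype[t_idx] <- sample.int(C, nT, replace = TRUE,
                                 prob = config$subtype_fractions)
    subtype[t_idx][stage[t_idx] == 0L] <- 0L

    # expected z per subject x ROI
    Gs <- lapply(config$true_sequences, trajectory_matrix, events = events)
    mu <- matrix(0, n, events$B)
    for (i in t_idx) {
      if (stage[i] > 0L) mu[i, ] <- Gs[[subtype[i]]][stage[i] + 1L, ]
    }
    # controls define the reference scale (unit z noise); targets scatter
    # around their trajectory with the configured noise
    noise_sd <- ifelse(group == "control", 1, config$z_noise_sd)
    zs <- mu + matrix(rnorm(n * events$B), n, events$B) * noise_sd
    vols <- pred - zs * matrix(cm$resid_sd, n, events$B, byrow = TRUE)
    colnames(vols) <- config$roi_names

    out <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%05d", seq_len(n)), group = group),
      cov,
      tibble::as_tibble(vols)
    )
    if (isTRUE(config$include_eligibility)) {
      is_target <- group == "target"
      out$mmse <- pmin(pmax(round(rnorm(n, 28.7, 1.3)), 22), 30)
      out$cdr_global <- ifelse(runif(n) < 0.03, 0.5, 0)
      out$lmdr <- pmin(pmax(round(rnorm(n, 12, 3.2)), 0), 25)
      out$suvr <- round(ifelse(is_target, rnorm(n, 1.33, 0.18),
                               rnorm(n, 0.99, 0.07)), 3)
      out$csf_ab42 <- round(ifelse(is_target, rnorm(n, 750, 160),
                                   rnorm(n, 1300, 220)), 1)
    }
    out$true_subtype <- subtype
    out$true_stage <- stage
    out
  })
}

#' Simulate longitudinal cognitive scores
#'
#' Generates, for every target subject with a ground-truth subtype label, the
#' linear random-intercept trajectory
#' `score_ij = beta0 + beta_age * age_i + gamma_c + delta_c * t_ij + b_i + e_ij`
#' with `b_i ~ N(0, sigma_b^2)`, `e_ij ~ N(0, sigma_e^2)`, for each
#' configured score. Dropout is monotone: once a subject misses a visit, all
#' later visits are missing; the baseline visit is always observed.
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (needs
#'   `true_subtype`).
#' @param config The same [cohort_config()].
#' @return A tibble with `subject_id`, `score`, `time` (yrs since baseline),
#'   `value`, `baseline_age`, `subtype` (0 = subtype zero).
#' @export
simulate_longitudinal <- function(cohort, config) {
  stopifnot(inherits(config, "zs_cohort_config"))
  assert_that(!is.null(config$longitudinal), "config has no longitudinal block")
  assert_that("true_subtype" %in% names(cohort),
              "cohort lacks subtype labels (true_subtype)")
  subj <- dplyr::filter(cohort, .data$group == "target",
                        !is.na(.data$true_subtype))
  lon <- config$longitudinal
  visits <- lon$visits
  V <- length(visits)
  with_seed_if(child_seed(config$seed, 2L), {
    ns <- nrow(subj)
    # monotone dropout: number of observed visits per subject
    n_obs <- rep(V, ns)
    if (lon$dropout > 0 && V > 1) {
      drop_draws <- matrix(runif(ns * (V - 1)) < lon$dropout, ns, V - 1)
      first_drop <- apply(drop_draws, 1, function(d) {
        w <- which(d)
        if (length(w) == 0) V else w[1]
      })
      n_obs <- pmin(n_obs, first_drop)
    }
    purrr::map_dfr(names(lon$scores), function(nm) {
      sc <- lon$scores[[nm]]
      b <- rnorm(ns, 0, sc$sigma_b)
      purrr::map_dfr(seq_len(ns), function(i) {
        t <- visits[seq_len(n_obs[i])]
        c_i <- subj$true_subtype[i] + 1L
        mu <- sc$beta0 + sc$beta_age * subj$age[i] + sc$gamma[c_i] +
          sc$delta[c_i] * t + b[i]
        tibble::tibble(
          subject_id = subj$subject_id[i], score = nm, time = t,
          value = mu + rnorm(length(t), 0, sc$sigma_e),
          baseline_age = subj$age[i], subtype = subj$true_subtype[i]
        )
      })
    })
  })
}
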