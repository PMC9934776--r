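# End-to-end pipeline: configuration, serialization, orchestration.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Inputs can be given as
#' CSV paths or in-memory tibbles (`cohort` / `longitudinal`); tibbles take
#' precedence.
#'
#' @param cohort,cohort_csv Cohort table (tibble) or path to its CSV.
#' @param longitudinal,longitudinal_csv Optional longitudinal score table or
#'   path.
#' @param output_dir Run directory for artifacts.
#' @param roi_names ROI columns used as biomarkers.
#' @param thresholds,z_max,sigma Event-model parameters (see [event_set()]
#'   and [sequence_likelihood()]).
#' @param n_max Maximum number of subtypes (default 4).
#' @param folds Cross-validation folds (default 10).
#' @param fit Options list from [fit_options()].
#' @param mcmc Named list `n_iter`, `burn_in`, `thin`.
#' @param eligibility Rules list for [apply_eligibility()], or NULL to skip
#'   filtering.
#' @param run_lme Fit longitudinal models? Requires longitudinal data.
#' @param lme_scores Score names to fit; default all present.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A `zs_pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, cohort_csv = NULL,
                            longitudinal = NULL, longitudinal_csv = NULL,
                            output_dir = tempfile("zsustain_run_"),
                            roi_names = default_rois(),
                            thresholds = c(1, 2), z_max = 5, sigma = 1,
                            n_max = 4L, folds = 10L,
                            fit = fit_options(),
                            mcmc = list(n_iter = 100000, burn_in = 10000,
                                        thin = 10),
                            eligibility = NULL,
                            run_lme = TRUE, lme_scores = NULL,
                            seed = 1L) {
  assert_that(n_max >= 1, "n_max must be at least 1")
  assert_that(folds >= 2, "folds must be at least 2")
  assert_that(!is.null(cohort) || !is.null(cohort_csv),
              "a cohort table or cohort_csv path is required")
  structure(
    list(cohort = cohort, cohort_csv = cohort_csv,
         longitudinal = longitudinal, longitudinal_csv = longitudinal_csv,
         output_dir = output_dir, roi_names = roi_names,
         thresholds = thresholds, z_max = z_max, sigma = sigma,
         n_max = as.integer(n_max), folds = as.integer(folds),
         fit = fit, mcmc = mcmc, eligibility = eligibility,
         run_lme = run_lme, lme_scores = lme_scores,
         seed = as.integer(seed)),
    class = "zs_pipeline_config"
  )
}

# Canonical JSON (recursively name-sorted) of the config's value fields;
# in-memory tables are represented by their column-wise digests so the hash
# changes iff any field changes.
canonical_config_json <- function(config) {
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else if (is.data.frame(x)) {
      lapply(as.list(x), function(col) unname(as.character(col)))
    } else {
      x
    }
  }
  fields <- config[setdiff(names(config), "output_dir")]
  jsonlite::toJSON(canon(fields), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonicalized (name-sorted) JSON representation of every
#' config field except the output directory.
#'
#' @param config A [pipeline_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(canonical_config_json(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize a subtype model to JSON
#'
#' Sequences are written as lists of `[roi, z-threshold]` pairs together with
#' fractions, noise scales and the event-set definition, so the model can be
#' re-read without the training data.
#'
#' @param model A `zs_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  ev <- model$events
  seqs <- lapply(model$sequences, function(s) {
    tb <- sequence_tbl(s, ev)
    lapply(seq_len(nrow(tb)), function(i) list(tb$roi[i], tb$z[i]))
  })
  obj <- list(
    n_subtypes = model$C,
    biomarkers = ev$biomarkers, thresholds = ev$thresholds, z_max = ev$z_max,
    sigma = model$sigma, fractions = model$fractions,
    sequences = seqs, loglik = model$loglik, n_subjects = model$n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subtype model from JSON
#'
#' Inverse of [write_model_json()]. The returned model carries no
#' responsibilities (they belong to the training data); recompute them with
#' [assign_subtypes()] if needed.
#'
#' @param path JSON file written by [write_model_json()].
#' @return A `zs_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ev <- event_set(unlist(obj$biomarkers),
                  thresholds = unlist(obj$thresholds),
                  z_max = obj$z_max)
  seqs <- lapply(obj$sequences, function(s) {
    vapply(s, function(p) {
      hit <- ev$events$roi == p[[1]] & abs(ev$events$z - p[[2]]) < 1e-12
      ev$events$event[hit][1]
    }, integer(1))
  })
  f <- unlist(obj$fractions)
  structure(
    list(C = obj$n_subtypes, sequences = seqs, fractions = f, events = ev,
         sigma = rep_len(unlist(obj$sigma), ev$B),
         loglik = obj$loglik,
         responsibilities = matrix(numeric(0), 0, obj$n_subtypes),
         n = obj$n_subjects, loglik_trace = numeric(0), iterations = NA_integer_),
    class = "zs_model"
  )
}

read_table_input <- function(tbl, path, what) {
  if (!is.null(tbl)) return(tibble::as_tibble(tbl))
  assert_that(file.exists(path), paste0(what, " CSV not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full disease-progression pipeline
#'
#' Executes, in order: optional eligibility filtering; control GLM fit and
#' z-scoring (targets are the modelling set); CVIC model selection; final
#' subtype fit at the selected C; MCMC sequence sampling; subtype/stage
#' assignment; cross-sectional group comparisons of covariates across
#' assigned subtypes; and (optionally) longitudinal mixed models per score.
#' Every intermediate artifact is written as plain CSV/JSON under
#' `output_dir`, plus a machine-readable `manifest.json` (config hash, stage
#' seeds, package version, stage status). All stochastic stages derive their
#' seed from the master seed, so re-running the same config on the same
#' inputs reproduces every output bit-for-bit. A failing stage aborts with
#' its name after writing a partial manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory and in-memory results
#'   (`zscores`, `cv`, `model`, `trace`, `assignments`, `stats`, `lme`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "zs_pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  manifest <- list(
    package = "zsustain",
    version = as.character(utils::packageVersion("zsustain")),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = list()
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }
  results <- list(output_dir = config$output_dir)

  cohort <- stage("load", read_table_input(config$cohort, config$cohort_csv,
                                           "cohort"))
  if (!is.null(config$eligibility)) {
    cohort <- stage("eligibility", {
      filt <- apply_eligibility(cohort, config$eligibility)
      readr::write_csv(attr(filt, "exclusion_log"), out("exclusion_log.csv"))
      filt
    })
  }
  zsc <- stage("preprocess", {
    glm <- fit_control_glm(cohort, rois = config$roi_names)
    jsonlite::write_json(
      list(n_controls = glm$n_controls,
           coefficients = glm$coefficients),
      out("control_glm.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    z_all <- compute_zscores(cohort, glm)
    readr::write_csv(z_all, out("zscores.csv"))
    z_all
  })
  z_target <- dplyr::filter(zsc, .data$group == "target")
  events <- event_set(config$roi_names, config$thresholds, config$z_max)

  cv <- stage("cross_validation", {
    cv <- run_cv(z_target, events, n_max = config$n_max,
                 folds = config$folds, sigma = config$sigma,
                 options = config$fit, seed = child_seed(config$seed, 11L))
    readr::write_csv(tidy.zs_cv(cv), out("cvic.csv"))
    readr::write_csv(cv$fold, out("cv_folds.csv"))
    cv
  })
  model <- stage("final_fit", {
    m <- fit_subtypes(z_target, C = cv$selected_C, events,
                      sigma = config$sigma, n_max = config$n_max,
                      options = config$fit,
                      seed = child_seed(config$seed, 12L))
    write_model_json(m, out("model.json"))
    m
  })
  trace <- stage("mcmc", {
    tr <- mcmc_sequences(z_target, model, n_iter = config$mcmc$n_iter,
                         burn_in = config$mcmc$burn_in,
                         thin = config$mcmc$thin,
                         seed = child_seed(config$seed, 13L))
    pp <- positional_probabilities(tr)
    for (c in seq_len(tr$C)) {
      readr::write_csv(dplyr::filter(pp, .data$subtype == c),
                       out(sprintf("positional_subtype%d.csv", c)))
    }
    tr
  })
  assignments <- stage("assignment", {
    a <- assign_subtypes(z_target, model)
    flat <- dplyr::select(a, -"stage_posterior")
    readr::write_csv(flat, out("assignments.csv"))
    readr::write_csv(stage_counts(a, E = events$E), out("stage_counts.csv"))
    readr::write_csv(stage_summary(a), out("stage_summary.csv"))
    a
  })
  stats_tbl <- stage("cross_sectional_stats", {
    joined <- dplyr::inner_join(
      dplyr::select(assignments, "subject_id", "ml_subtype"),
      cohort, by = "subject_id")
    s <- subtype_comparisons(joined)
    readr::write_csv(s, out("subtype_comparisons.csv"))
    s
  })
  lme_fits <- NULL
  if (isTRUE(config$run_lme) &&
      (!is.null(config$longitudinal) || !is.null(config$longitudinal_csv))) {
    lme_fits <- stage("longitudinal_lme", {
      lon <- read_table_input(config$longitudinal, config$longitudinal_csv,
                              "longitudinal")
      scores <- config$lme_scores %||% unique(lon$score)
      fits <- purrr::map(setNames(scores, scores), function(sc) {
        fit <- fit_decline_lme(lon, score = sc)
        readr::write_csv(fit$coefficients,
                         out(sprintf("lme_%s_coefficients.csv", sc)))
        readr::write_csv(decline_summary(fit),
                         out(sprintf("lme_%s_decline.csv", sc)))
        fit
      })
      fits
    })
  }
  write_manifest()
  results <- c(results,
               list(zscores = zsc, cv = cv, model = model, trace = trace,
                    assignments = assignments, stats = stats_tbl,
                    lme = lme_fits, manifest = manifest))
  invisible(results)
}

#' Compare baseline variables across assigned subtypes
#'
#' ANOVA (from raw-data group summaries) for continuous variables and
#' Pearson chi-square for categorical ones, Holm-adjusted as one family —
#' the cross-sectional characteristics comparison, computed on a cohort
#' joined with its subtype assignments.
#'
#' @param data Tibble with `ml_subtype` and the variables.
#' @param continuous,categorical Variable names; defaults cover the standard
#'   covariates present in the table.
#' @return Tibble like [table1_tests()].
#' @export
subtype_comparisons <- function(data,
                                continuous = intersect(c("age", "education",
                                                         "mmse", "suvr"),
                                                       names(data)),
                                categorical = intersect("sex", names(data))) {
  rows <- list()
  for (v in continuous) {
    sm <- dplyr::summarise(dplyr::group_by(data, .data$ml_subtype),
                           n = sum(!is.na(.data[[v]])),
                           mean = mean(.data[[v]], na.rm = TRUE),
                           sd = sd(.data[[v]], na.rm = TRUE),
                           .groups = "drop")
    r <- anova_from_summary(sm[, c("n", "mean", "sd")])
    rows[[v]] <- tibble::tibble(variable = v, test = r$test,
                                statistic = r$statistic, df = r$df1,
                                p_value = r$p_value)
  }
  for (v in categorical) {
    tab <- table(data[[v]], data$ml_subtype)
    r <- pearson_chi2(as.matrix(tab))
    rows[[v]] <- tibble::tibble(variable = v, test = r$test,
                                statistic = r$statistic, df = r$df,
                                p_value = r$p_value)
  }
  res <- dplyr::bind_rows(rows)
  res$p_holm <- holm_adjust(res$p_value)
  res
}

#' Write a synthetic cohort and its ground truth as CSV
#'
#' The cohort is written without the ground-truth columns; the latent
#' subtype/stage labels go to a sidecar file so pipelines can run blind.
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param path Cohort CSV path; the sidecar gets suffix
#'   `_ground_truth.csv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  gt_cols <- intersect(c("true_subtype", "true_stage"), names(cohort))
  blind <- cohort[, setdiff(names(cohort), gt_cols)]
  readr::write_csv(blind, path)
  sidecar <- sub("\\.csv$", "_ground_truth.csv", path)
  readr::write_csv(cohort[, c("subject_id", gt_cols)], sidecar)
  invisible(c(cohort = path, ground_truth = sidecar))
}
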