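# Independent oracles and shared fixtures. Each oracle re-derives a quantity
# from its definition, never through the package's computational path.

# Staircase ordering: biomarkers reach z=1 then z=2 one after another, in the
# given biomarker order. stair(1:B) and stair(B:1) are maximally separated
# valid orderings.
stair <- function(ord) as.integer(c(rbind(2L * ord - 1L, 2L * ord)))

# Brute-force log marginal likelihood: linear-domain summation over stages,
# trajectories evaluated through the definitional R path.
oracle_log_marginal <- function(x, sequence, events, sigma = 1) {
  sigma <- rep_len(sigma, events$B)
  terms <- vapply(0:events$E, function(k) {
    mu <- vapply(seq_len(events$B), function(b) {
      expected_trajectory(sequence, events, b, k)
    }, numeric(1))
    prod(dnorm(x, mu, sigma))
  }, numeric(1))
  log(mean(terms))
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# combined (tie-free) sample to the two groups.
oracle_mwu_exact_p <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  n <- length(a)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  us <- vapply(utils::combn(length(pooled), n, simplify = FALSE), u_of,
               numeric(1))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Definitional Holm step-down adjustment.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Type-7 sample quantile from first principles (sort + linear interpolation).
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# GLS fixed effects under compound-symmetry covariance with known variance
# components, for balanced complete longitudinal data.
oracle_gls_cs <- function(X, y, subject, sigma_b, sigma_e) {
  ids <- unique(subject)
  A <- matrix(0, ncol(X), ncol(X))
  v <- numeric(ncol(X))
  for (id in ids) {
    idx <- which(subject == id)
    Vi <- diag(sigma_e^2, length(idx)) + sigma_b^2
    Vinv <- solve(Vi)
    Xi <- X[idx, , drop = FALSE]
    A <- A + t(Xi) %*% Vinv %*% Xi
    v <- v + t(Xi) %*% Vinv %*% y[idx]
  }
  drop(solve(A, v))
}

# Small synthetic cohort in z-score space: simulate, fit the control GLM,
# return target z-scores and ground truth.
make_z_cohort <- function(B = 3, n_targets = 200, n_controls = 80,
                          true_sequences = NULL, subtype_fractions = NULL,
                          stage0_mass = 0, z_noise_sd = 1, seed = 1) {
  rois <- paste0("R", seq_len(B))
  if (is.null(true_sequences)) true_sequences <- list(stair(seq_len(B)))
  if (is.null(subtype_fractions)) {
    subtype_fractions <- rep(1 / length(true_sequences), length(true_sequences))
  }
  cfg <- cohort_config(
    n_controls = n_controls, n_targets = n_targets, roi_names = rois,
    true_sequences = true_sequences, subtype_fractions = subtype_fractions,
    stage0_mass = stage0_mass, z_noise_sd = z_noise_sd,
    longitudinal = FALSE, seed = seed
  )
  cohort <- simulate_cohort(cfg)
  glm <- fit_control_glm(cohort, rois = rois)
  z <- compute_zscores(cohort, glm)
  list(
    config = cfg, cohort = cohort, glm = glm,
    z_target = dplyr::filter(z, group == "target"),
    truth = dplyr::filter(cohort, group == "target")[, c("subject_id",
                                                         "true_subtype",
                                                         "true_stage")],
    events = cfg$events, rois = rois
  )
}
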