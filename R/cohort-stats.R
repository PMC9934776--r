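# Cross-sectional comparisons across subtype groups.

#' Pearson chi-square test of a contingency table
#'
#' Classic Pearson statistic `X2 = sum (O - E)^2 / E` with expected counts
#' from the product of marginals, `df = (r - 1)(c - 1)`, upper-tail p-value,
#' and no continuity correction.
#'
#' @param counts Numeric matrix of non-negative counts with positive
#'   marginals.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @examples
#' pearson_chi2(rbind(c(10, 0), c(0, 10))) # X2 = 20, df = 1
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0) && all(is.finite(counts)),
              "counts must be non-negative and finite")
  assert_that(all(rowSums(counts) > 0) && all(colSums(counts) > 0),
              "contingency table has a zero marginal")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(test = "pearson_chi2",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the between- and within-group sums of squares from per-group
#' `(n, mean, sd)` and forms `F = MSB / MSW` with `df1 = g - 1`,
#' `df2 = sum(n) - g`. Identical (to rounding of the summaries) to a classic
#' one-way ANOVA on the raw data; used to re-test printed cohort tables.
#'
#' @param groups Data frame with columns `n`, `mean`, `sd`, one row per
#'   group (>= 2 groups, each `n >= 2`, all `sd > 0`).
#' @return One-row tibble: `test`, `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_from_summary <- function(groups) {
  groups <- tibble::as_tibble(groups)
  assert_that(all(c("n", "mean", "sd") %in% names(groups)),
              "groups needs columns n, mean, sd")
  g <- nrow(groups)
  assert_that(g >= 2, "at least 2 groups are required")
  assert_that(all(groups$n >= 2), "each group needs n >= 2")
  assert_that(all(groups$sd > 0), "group sd must be positive when n >= 2")
  N <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1) * groups$sd^2)
  f <- (ssb / (g - 1)) / (ssw / (N - g))
  tibble::tibble(test = "anova_summary", statistic = f,
                 df1 = g - 1, df2 = N - g,
                 p_value = pf(f, g - 1, N - g, lower.tail = FALSE))
}

#' Two-tailed Mann-Whitney U test
#'
#' The U statistic uses midranks for ties. The two-sided p-value is exact
#' (enumeration of the U distribution) when `n * m <= 400` and there are no
#' ties, and otherwise a normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric samples (both nonempty).
#' @return One-row tibble: `test`, `statistic` (U for sample `a`), `p_value`,
#'   `exact` (logical).
#' @export
mann_whitney_u <- function(a, b) {
  assert_that(length(a) > 0 && length(b) > 0, "both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 400
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  tibble::tibble(test = "mann_whitney_u",
                 statistic = unname(ht$statistic),
                 p_value = min(unname(ht$p.value), 1),
                 exact = exact)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the raw p-values ascending, sets
#' `adj_i = max(adj_{i-1}, (m - i + 1) p_i)` capped at 1, and returns the
#' adjusted values in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03, 0.06, 0.06
#' @export
holm_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Printed cohort characteristics of a preclinical amyloid-positive cohort
#'
#' The published characteristics table of the 1240-person amyloid-positive
#' cohort stratified by atrophy subtype (subtype zero, Typical, Cortical,
#' Subcortical): per-group summary statistics for continuous variables and
#' per-category counts for categorical ones, transcribed as printed. These
#' summaries are the *input* to [table1_tests()], which recomputes the
#' statistical column from them. APOE e4 rows are allele counts (0/1/2) with
#' the few missing genotypes excluded.
#'
#' @return Long tibble with `variable`, `type` ("continuous"/"categorical"),
#'   `group`, and `n`/`mean`/`sd` (continuous) or `category`/`count`
#'   (categorical).
#' @export
a4_table1_summary <- function() {
  groups <- c("subtype_zero", "typical", "cortical", "subcortical")
  n <- c(717, 170, 179, 174)
  cont <- function(variable, mean, sd) {
    tibble::tibble(variable = variable, type = "continuous", group = groups,
                   n = n, mean = mean, sd = sd,
                   category = NA_character_, count = NA_real_)
  }
  cat_ <- function(variable, category, count) {
    tibble::tibble(variable = variable, type = "categorical",
                   group = rep(groups, times = length(category)),
                   n = NA_real_, mean = NA_real_, sd = NA_real_,
                   category = rep(category, each = length(groups)),
                   count = as.numeric(t(count)))
  }
  female <- c(445, 98, 103, 84)
  famhx <- c(525, 130, 136, 133)
  dplyr::bind_rows(
    cont("age", c(71.9, 72.4, 72.6, 71.6), c(4.6, 5.3, 5.2, 4.9)),
    cat_("female", c("F", "M"), rbind(female, n - female)),
    cont("education", c(16.6, 16.0, 16.6, 16.8), c(2.8, 2.8, 2.8, 2.9)),
    cat_("family_history", c("yes", "no"), rbind(famhx, n - famhx)),
    cat_("apoe_e4_alleles", c("0", "1", "2"),
         rbind(c(297, 62, 73, 74), c(364, 92, 82, 83), c(49, 12, 23, 17))),
    cont("pet_suvr", c(1.32, 1.35, 1.35, 1.33), c(0.17, 0.19, 0.19, 0.18)),
    cont("pacc", c(-0.15, -0.89, -1.30, -0.13), c(2.57, 2.72, 3.04, 2.49)),
    cont("cdr_sb", c(0.05, 0.08, 0.06, 0.07), c(0.15, 0.19, 0.16, 0.22)),
    cont("mmse", c(28.80, 28.55, 28.65, 28.78), c(1.23, 1.38, 1.41, 1.21)),
    cont("digit_symbol", c(43.52, 41.08, 40.55, 42.29),
         c(8.91, 9.19, 8.82, 8.39)),
    cont("cfi_total", c(3.43, 4.29, 4.81, 3.93), c(3.10, 3.83, 4.17, 3.68))
  )
}

#' Recompute a characteristics-table statistical column from summaries
#'
#' For every variable in a long summary table (format of
#' [a4_table1_summary()]): continuous rows get a one-way
#' [anova_from_summary()] across the groups, categorical rows a
#' [pearson_chi2()] on the category-by-group counts. The Holm-Bonferroni
#' adjustment is applied jointly across all variables (one family).
#'
#' @param summary_tbl Long summary tibble; see [a4_table1_summary()].
#' @return Tibble with one row per variable: `variable`, `test`,
#'   `statistic`, `df`, `p_value`, `p_holm`.
#' @export
table1_tests <- function(summary_tbl) {
  summary_tbl <- tibble::as_tibble(summary_tbl)
  vars <- unique(summary_tbl$variable)
  res <- purrr::map_dfr(vars, function(v) {
    rows <- dplyr::filter(summary_tbl, .data$variable == v)
    type <- rows$type[1]
    if (identical(type, "continuous")) {
      r <- anova_from_summary(rows[, c("n", "mean", "sd")])
      tibble::tibble(variable = v, test = r$test, statistic = r$statistic,
                     df = r$df1, p_value = r$p_value)
    } else if (identical(type, "categorical")) {
      m <- tidyr::pivot_wider(rows[, c("group", "category", "count")],
                              names_from = "group", values_from = "count")
      r <- pearson_chi2(as.matrix(m[, -1]))
      tibble::tibble(variable = v, test = r$test, statistic = r$statistic,
                     df = r$df, p_value = r$p_value)
    } else {
      stop("malformed row spec for variable '", v, "': unknown type '",
           type, "'", call. = FALSE)
    }
  })
  res$p_holm <- holm_adjust(res$p_value)
  res
}

#' Pairwise Mann-Whitney comparisons of a score across subtype groups
#'
#' All pairwise two-tailed Mann-Whitney U tests of `score` between levels of
#' `group`, Holm-adjusted as one family.
#'
#' @param data Data frame with the score and grouping columns.
#' @param score,group Column names (strings).
#' @return Tibble with `group_a`, `group_b`, `statistic`, `p_value`,
#'   `p_holm`.
#' @export
pairwise_mann_whitney <- function(data, score, group) {
  data <- tibble::as_tibble(data)
  levs <- sort(unique(data[[group]]))
  assert_that(length(levs) >= 2, "need at least two groups")
  pairs <- utils::combn(as.character(levs), 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    a <- data[[score]][data[[group]] == pr[1]]
    b <- data[[score]][data[[group]] == pr[2]]
    r <- mann_whitney_u(a[!is.na(a)], b[!is.na(b)])
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   statistic = r$statistic, p_value = r$p_value)
  })
  res$p_holm <- holm_adjust(res$p_value)
  res
}
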