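test_that("Pearson chi-square matches its closed form", {
  # perfectly proportional table: no association
  prop <- outer(c(30, 70), c(0.2, 0.5, 0.3))
  r <- pearson_chi2(prop)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  r2 <- pearson_chi2(rbind(c(10, 0), c(0, 10)))
  expect_equal(r2$statistic, 20)
  expect_identical(as.integer(r2$df), 1L)

  # sex-by-subtype counts from the published cohort table
  sex <- rbind(female = c(445, 98, 103, 84), male = c(272, 72, 76, 90))
  r3 <- pearson_chi2(sex)
  expect_equal(r3$statistic, 11.322, tolerance = 1e-3)
  expect_identical(as.integer(r3$df), 3L)

  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "zero marginal")
})

test_that("summary-statistic ANOVA equals raw-data ANOVA", {
  g <- tibble::tibble(n = c(10, 12, 9), mean = c(5, 5, 5), sd = c(1, 2, 1.5))
  expect_equal(anova_from_summary(g)$statistic, 0, tolerance = 1e-12)
  expect_equal(anova_from_summary(g)$p_value, 1, tolerance = 1e-12)

  # two groups: F equals the squared pooled-variance t statistic
  withr::with_seed(41, {
    a <- rnorm(14, 1, 2)
    b <- rnorm(20, 0, 2)
  })
  g2 <- tibble::tibble(n = c(14, 20), mean = c(mean(a), mean(b)),
                       sd = c(sd(a), sd(b)))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(anova_from_summary(g2)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)

  # agreement with classical one-way ANOVA on raw data
  withr::with_seed(42, {
    y <- c(rnorm(15, 0), rnorm(18, 0.5), rnorm(12, -0.3))
    grp <- factor(rep(1:3, c(15, 18, 12)))
  })
  sm <- tibble::tibble(
    n = tapply(y, grp, length), mean = tapply(y, grp, mean),
    sd = tapply(y, grp, sd)
  )
  raw <- anova(lm(y ~ grp))
  expect_equal(anova_from_summary(sm)$statistic, raw$`F value`[1],
               tolerance = 1e-9)
  expect_equal(anova_from_summary(sm)$p_value, raw$`Pr(>F)`[1],
               tolerance = 1e-9)

  # published cognitive-composite summaries across the four subtype groups
  pacc <- tibble::tibble(n = c(717, 170, 179, 174),
                         mean = c(-0.15, -0.89, -1.30, -0.13),
                         sd = c(2.57, 2.72, 3.04, 2.49))
  expect_equal(anova_from_summary(pacc)$statistic, 11.51, tolerance = 1e-2)

  expect_error(anova_from_summary(tibble::tibble(n = 5, mean = 1, sd = 1)),
               "at least 2 groups")
  expect_error(anova_from_summary(tibble::tibble(n = c(5, 5), mean = c(1, 2),
                                                 sd = c(1, 0))),
               "sd must be positive")
})

test_that("Mann-Whitney U is exact without ties and identity-consistent", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_true(r$exact)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)

  withr::with_seed(43, {
    for (rep in 1:50) {
      n <- sample(2:6, 1)
      m <- sample(2:6, 1)
      pool <- sample(1:60, n + m)
      a <- pool[1:n]
      b <- pool[-(1:n)]
      got <- mann_whitney_u(a, b)
      expect_equal(got$p_value, oracle_mwu_exact_p(a, b), tolerance = 1e-12)
      # U_a + U_b = n * m
      u_b <- mann_whitney_u(b, a)$statistic
      expect_equal(unname(got$statistic + u_b), n * m)
    }
  })
})

test_that("Holm adjustment matches its step-down definition", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15))

  withr::with_seed(44, {
    for (rep in 1:50) {
      p <- runif(sample(1:12, 1))
      adj <- holm_adjust(p)
      expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      # monotone when re-sorted by raw p
      expect_true(!is.unsorted(adj[order(p)]))
    }
  })
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("the published characteristics table is reproduced from summaries", {
  res <- table1_tests(a4_table1_summary())
  expect_identical(nrow(res), 11L)
  expect_true(all(res$p_holm >= res$p_value))

  # the sex comparison adjusts to .08; the cognitive scores stay < .001
  expect_equal(round(res$p_holm[res$variable == "female"], 2), 0.08)
  expect_lt(res$p_holm[res$variable == "pacc"], 0.001)
  expect_lt(res$p_holm[res$variable == "digit_symbol"], 0.001)
  expect_lt(res$p_holm[res$variable == "cfi_total"], 0.001)
  # demographic rows stay non-significant, as printed
  expect_gt(res$p_holm[res$variable == "age"], 0.05)
  expect_gt(res$p_holm[res$variable == "mmse"], 0.05)

  # a single-row family needs no adjustment
  one <- dplyr::filter(a4_table1_summary(), variable == "age")
  r1 <- table1_tests(one)
  expect_equal(r1$p_holm, r1$p_value)

  bad <- tibble::tibble(variable = "x", type = "weird", group = "g",
                        n = 1, mean = 1, sd = 1,
                        category = NA_character_, count = NA_real_)
  expect_error(table1_tests(bad), "malformed row spec")
})

test_that("pairwise Mann-Whitney comparisons are Holm-adjusted as a family", {
  withr::with_seed(45, {
    d <- tibble::tibble(
      score = c(rnorm(40, 0), rnorm(40, 1.2), rnorm(40, 0.1)),
      grp = rep(c("a", "b", "c"), each = 40)
    )
  })
  res <- pairwise_mann_whitney(d, "score", "grp")
  expect_identical(nrow(res), 3L)
  expect_equal(res$p_holm, holm_adjust(res$p_value))
  expect_true(all(res$p_holm >= res$p_value))
})
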