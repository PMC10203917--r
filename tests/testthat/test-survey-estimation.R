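# Design-based estimation: weighted means, Taylor-linearized SEs against an
# independent oracle, weighted percentiles, direct age standardization,
# weighted regression, and the chi-square homogeneity test.

test_that("weighted mean follows the ratio definition and its edge cases", {
  expect_equal(weighted_mean(c(2, 4, 9), rep(5, 3)), 5)
  expect_equal(weighted_mean(c(0, 100), c(1, 3)), 75)
  expect_equal(weighted_mean(7.3, 2), 7.3)
  expect_error(weighted_mean(numeric(), numeric()), "empty")
  expect_error(weighted_mean(c(1, NA), c(1, 1)), "missing")
  expect_error(weighted_mean(1:2, c(1, 0)), "> 0")
  # invariance to rescaling all weights
  set.seed(11)
  y <- rnorm(50); w <- runif(50, 0.5, 3)
  expect_equal(weighted_mean(y, w), weighted_mean(y, w * 17.3))
})

test_that("linearized SE of the mean reduces to the textbook SRS formula", {
  set.seed(12)
  y <- rnorm(40, 10, 3)
  # one stratum, every observation its own PSU, equal weights
  r <- taylor_se_mean(y, rep(1, 40), rep(1, 40), seq_len(40))
  expect_equal(r$mean, mean(y))
  expect_equal(r$se, sd(y) / sqrt(40), tolerance = 1e-12)
  expect_equal(r$df, 39)
  # all values identical: zero variance
  r0 <- taylor_se_mean(rep(5, 12), runif(12, 1, 2),
                       rep(1:2, each = 6), rep(1:3, 4))
  expect_equal(r0$se, 0)
})

test_that("linearized SEs match the independent oracle on random designs", {
  set.seed(13)
  worst <- 0
  for (i in 1:120) {
    d <- random_design(n_strata = sample(2:4, 1), psus = sample(2:3, 1),
                       n_per_psu = sample(3:10, 1))
    dom <- if (i %% 3 == 0) runif(nrow(d)) < 0.7 else rep(TRUE, nrow(d))
    if (!any(dom)) dom[1] <- TRUE
    got <- taylor_se_mean(d$y, d$w, d$stratum, d$psu, domain = dom)
    want <- oracle_taylor_se(d$y, d$w, d$stratum, d$psu, domain = dom)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    worst <- max(worst, abs(got$se - want$se) / want$se)
  }
  expect_lt(worst, 1e-10)
})

test_that("singleton-PSU policies fail, collapse, or center as configured", {
  d <- random_design(3, 2, 5)
  d$psu[d$stratum == 2] <- 1   # stratum 2 becomes a single PSU
  expect_error(taylor_se_mean(d$y, d$w, d$stratum, d$psu), "singleton")
  se_col <- taylor_se_mean(d$y, d$w, d$stratum, d$psu,
                           lonely_psu = "collapse")$se
  se_cen <- taylor_se_mean(d$y, d$w, d$stratum, d$psu,
                           lonely_psu = "center")$se
  expect_gt(se_col, 0)
  expect_gt(se_cen, 0)
})

test_that("weighted percentiles use the smallest-value-reaching-p rule", {
  expect_equal(weighted_percentile(1:100, rep(1, 100), 0.5), 50)
  expect_equal(weighted_percentile(rep(3.2, 9), runif(9, 1, 2),
                                   c(0.1, 0.5, 0.95)), rep(3.2, 3))
  # 96% of the mass on one value pins the 95th percentile there
  expect_equal(weighted_percentile(c(1, 7, 9), c(2, 96, 2), 0.95), 7)
  expect_equal(weighted_percentile(c(1, 7, 9), c(2, 96, 2), 0.99), 9)
  expect_error(weighted_percentile(numeric(), numeric(), 0.5), "empty")
  # unsorted input with ties is deterministic
  expect_equal(weighted_percentile(c(5, 2, 5, 1), c(1, 1, 1, 1), 0.5), 2)
})

test_that("direct age standardization combines bands with fixed weights", {
  mk <- function(est, se) list(estimate = est, se = se, df = 14, n = 100)
  bands <- list("20-39" = mk(70, 1), "40-64" = mk(60, 1),
                "65-79" = mk(50, 1))
  std <- age_standardize(bands)
  expect_equal(std$estimate, 62.18, tolerance = 1e-12)
  expect_equal(std$se, sqrt(sum(std_pop_us2018()^2)), tolerance = 1e-12)
  # equal band means collapse to the common mean
  eq <- list("20-39" = mk(64, 2), "40-64" = mk(64, 1), "65-79" = mk(64, 0.5))
  expect_equal(age_standardize(eq)$estimate, 64)
  # zero band SEs give a zero standardized SE
  z <- list("20-39" = mk(70, 0), "40-64" = mk(60, 0), "65-79" = mk(50, 0))
  expect_equal(age_standardize(z)$se, 0)
  expect_error(age_standardize(bands[1:2]), "65-79")
})

test_that("age bands label ages per the standard population scheme", {
  expect_equal(age_band(c(20, 39, 40, 64, 65, 79)),
               c("20-39", "20-39", "40-64", "40-64", "65-79", "65-79"))
  expect_true(is.na(age_band(85)))
})

test_that("survey-weighted regression equals OLS for an unclustered
          equal-weight design", {
  set.seed(14)
  n <- 80
  d <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = runif(n),
                  stratum = 1, psu = seq_len(n), weight = 1)
  fit <- svy_lm(y ~ x1 + x2, svy_design(d))
  ols <- lm(y ~ x1 + x2, d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
  # constant outcome: slope 0, p = 1
  d$y <- 3
  fit0 <- svy_lm(y ~ x1, svy_design(d))
  expect_equal(unname(fit0$coefficients["x1"]), 0)
  expect_equal(unname(fit0$p["x1"]), 1)
  # collinear block is reported
  d$y <- rnorm(n); d$x3 <- d$x1 * 2
  expect_error(svy_lm(y ~ x1 + x3, svy_design(d)), "collinear")
})

test_that("two-cycle unadjusted trend equals the weighted mean difference", {
  set.seed(15)
  n <- 60
  d <- data.frame(cycle = rep(c("a", "b"), each = n),
                  y = c(rnorm(n, 50), rnorm(n, 47)),
                  w = runif(2 * n, 0.5, 2),
                  stratum = rep(rep(1:3, each = n / 3), 2),
                  psu = rep(rep(1:2, n / 2 * 3), length.out = 2 * n))
  d$stratum <- paste(d$cycle, d$stratum)   # cycle-specific strata
  names(d)[names(d) == "w"] <- "weight"
  tr <- trend_regression(d, "y")
  m1 <- weighted_mean(d$y[d$cycle == "a"], d$weight[d$cycle == "a"])
  m2 <- weighted_mean(d$y[d$cycle == "b"], d$weight[d$cycle == "b"])
  expect_equal(tr$slope, m2 - m1, tolerance = 1e-10)
})

test_that("chi-square homogeneity test reproduces the classical statistic
          and degenerates correctly", {
  # hand-computed Pearson value for (20,10 / 10,20)
  m <- matrix(c(20, 10, 10, 20), 2, 2, byrow = TRUE)
  got <- category_homogeneity_test(m)
  expect_equal(got$statistic, 20 / 3, tolerance = 1e-12)
  want <- suppressWarnings(chisq.test(m, correct = FALSE))
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  # identical distributions across cycles: statistic 0, p 1
  eq <- matrix(c(30, 20, 30, 20), 2, 2, byrow = TRUE)
  r <- category_homogeneity_test(eq)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("design-based chi-square applies a positive design-effect
          correction", {
  set.seed(16)
  n <- 600
  d <- data.frame(stratum = rep(1:5, each = n / 5),
                  psu = rep(rep(1:2, each = n / 10), 5),
                  weight = exp(rnorm(n, 0, 0.4)))
  d$cat <- sample(c("x", "y", "z"), n, TRUE, c(0.4, 0.4, 0.2))
  d$cycle <- sample(c("c1", "c2"), n, TRUE)
  des <- svy_design(d)
  r <- category_homogeneity_test(d$cat, d$cycle, des)
  expect_gt(r$deff, 0)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_equal(r$df, 2)
})

test_that("design-based chi-square holds its size under the null", {
  set.seed(17)
  pvals <- replicate(200, {
    n <- 240
    d <- data.frame(stratum = rep(1:4, each = n / 4),
                    psu = rep(rep(1:2, each = n / 8), 4),
                    weight = exp(rnorm(n, 0, 0.3)))
    d$cat <- sample(c("x", "y"), n, TRUE)
    d$cycle <- rep(c("c1", "c2"), n / 2)
    category_homogeneity_test(d$cat, d$cycle, svy_design(d))$p_value
  })
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.10)
})
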