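# LE8 component scorers: ladder boundaries, deductions, averaging rules,
# the overall score, categories, and oracle equivalence.

test_that("physical-activity ladder covers every rung and boundary", {
  cases <- rbind(c(0, 0, 0), c(1, 0, 20), c(29, 0, 20), c(30, 0, 40),
                 c(59, 0, 40), c(60, 0, 60), c(89, 0, 60), c(90, 0, 80),
                 c(119, 0, 80), c(120, 0, 90), c(149, 0, 90), c(150, 0, 100),
                 c(100, 30, 100),   # 100 + 2*30 = 160
                 c(0, 60, 90))      # vigorous counts double: 120
  expect_equal(score_pa(cases[, 1], cases[, 2]), cases[, 3])
  expect_equal(score_pa(100, 30, multiplier = 1), 90)  # 130 without doubling
  expect_true(is.na(score_pa(NA, 10)))
  expect_error(score_pa(-5, 0), "range")
})

test_that("nicotine scoring applies base ladder, current-use override and
          secondhand deduction", {
  expect_equal(score_nicotine("never", FALSE, FALSE), 100)
  expect_equal(score_nicotine("former_quit_ge5y", FALSE, FALSE), 75)
  expect_equal(score_nicotine("former_quit_1to5y", FALSE, FALSE), 50)
  expect_equal(score_nicotine("former_quit_lt1y", FALSE, FALSE), 25)
  expect_equal(score_nicotine("current", FALSE, FALSE), 0)
  # household exposure deducts 20 from positive bases only
  expect_equal(score_nicotine("never", FALSE, TRUE), 80)
  expect_equal(score_nicotine("former_quit_lt1y", FALSE, TRUE), 5)
  expect_equal(score_nicotine("current", FALSE, TRUE), 0)
  # any inhaled product in the past 30 days means current use
  expect_equal(score_nicotine("never", TRUE, FALSE), 0)
  expect_true(is.na(score_nicotine(NA, FALSE, FALSE)))
  expect_true(is.na(score_nicotine("never", NA, FALSE)))
})

test_that("sleep ladder scores all duration bands", {
  hours <- c(8, 7, 8.9, 9, 9.9, 6, 6.9, 5, 5.9, 10, 12, 4, 4.9, 3.9, 0)
  want <- c(100, 100, 100, 90, 90, 70, 70, 40, 40, 40, 40, 20, 20, 0, 0)
  expect_equal(score_sleep(hours), want)
  expect_error(score_sleep(24), "range")
})

test_that("BMI ladder scores from measured height and weight", {
  # BMI 24.9 via height 200 cm, weight 99.6 kg
  expect_equal(score_bmi(200, 99.6), 100)
  expect_equal(score_bmi(200, 100), 70)    # exactly 25.0
  expect_equal(score_bmi(160, 76.8), 70)   # 30.0 - eps stays in band? 76.8/2.56 = 30 -> 30
  bmi_of <- function(b) score_bmi(100, b)  # 1 m tall: weight = BMI
  expect_equal(bmi_of(c(24.9, 25, 29.9, 30, 34.9, 35, 39.9, 40, 55)),
               c(100, 70, 70, 30, 30, 15, 15, 0, 0))
})

test_that("lipid ladder and treatment deduction", {
  expect_equal(score_lipids(c(129, 130, 159, 160, 189, 190, 219, 220, 225),
                            rep(FALSE, 9)),
               c(100, 60, 60, 40, 40, 20, 20, 0, 0))
  expect_equal(score_lipids(129, TRUE), 80)
  expect_equal(score_lipids(225, TRUE), 0)   # deduction never goes negative
  expect_equal(score_lipids(219, TRUE), 0)   # 20 - 20 floors at 0
})

test_that("glucose scoring distinguishes diabetes status and falls back to
          HbA1c", {
  expect_equal(score_glucose(FALSE, FALSE, 95, 5.0), 100)
  expect_equal(score_glucose(FALSE, FALSE, 99, NA), 100)
  expect_equal(score_glucose(FALSE, FALSE, 100, NA), 60)
  expect_equal(score_glucose(FALSE, FALSE, 125, NA), 60)
  # fasting glucose missing: HbA1c rules
  expect_equal(score_glucose(FALSE, FALSE, NA, 5.6), 100)
  expect_equal(score_glucose(FALSE, FALSE, NA, 5.7), 60)
  # diabetes by history, meds, or diabetic-range glycemia: HbA1c control
  expect_equal(score_glucose(TRUE, FALSE, NA, 6.8), 40)
  expect_equal(score_glucose(FALSE, TRUE, NA, 6.8), 40)
  expect_equal(score_glucose(FALSE, FALSE, 126, 6.8), 40)
  expect_equal(score_glucose(FALSE, FALSE, NA, 6.5), 40)
  expect_equal(score_glucose(TRUE, FALSE, NA, c(7, 7.9, 8, 8.9, 9, 9.9, 10)),
               c(30, 30, 20, 20, 10, 10, 0))
  expect_true(is.na(score_glucose(TRUE, FALSE, 110, NA)))
  expect_true(is.na(score_glucose(FALSE, FALSE, NA, NA)))
})

test_that("blood-pressure averaging uses the documented reading rule", {
  expect_equal(average_bp(c(130, 120, 110), c(80, 75, 70)),
               list(sbp = 115, dbp = 72.5))
  expect_equal(average_bp(c(120, 120, 120), c(80, 80, 80))$sbp, 120)
  expect_equal(average_bp(c(118, NA, NA), c(76, NA, NA)),
               list(sbp = 118, dbp = 76))
  expect_equal(average_bp(c(124, 120, NA), c(82, 78, NA)),
               list(sbp = 122, dbp = 80))
  m <- matrix(c(130, 120, 110, 118, NA, NA), 2, 3, byrow = TRUE)
  expect_equal(average_bp(m, m - 40)$sbp, c(115, 118))
})

test_that("blood-pressure staging takes the worse reading and deducts for
          treatment", {
  expect_equal(score_bp(118, 78, FALSE), 100)
  expect_equal(score_bp(118, 78, TRUE), 80)
  expect_equal(score_bp(125, 78, FALSE), 75)
  expect_equal(score_bp(125, 92, FALSE), 25)   # diastolic drives the stage
  expect_equal(score_bp(135, 70, FALSE), 50)
  expect_equal(score_bp(145, 70, FALSE), 25)
  expect_equal(score_bp(160, 70, FALSE), 0)
  expect_equal(score_bp(110, 100, FALSE), 0)
  expect_equal(score_bp(162, 102, TRUE), 0)
  expect_error(score_bp(110, 115, FALSE), "diastolic")
})

test_that("diet percentile bands respect tie-to-higher-band convention", {
  cuts <- c(40, 50, 60, 75)
  expect_equal(score_diet(c(39.9, 40, 49, 50, 60, 74, 75, 90), cuts),
               c(0, 25, 25, 50, 80, 80, 100, 100))
  # degenerate population: all HEI equal, everyone reaches every cutoff
  hei <- rep(55, 40)
  cuts2 <- diet_percentile_cutoffs(hei, rep(1, 40))
  expect_equal(unique(cuts2), 55)
  expect_equal(score_diet(hei, cuts2), rep(100, 40))
})

test_that("overall score is the exact mean of the eight components and
          categories use half-open bounds", {
  s <- data.frame(diet = 41, pa = 57, nicotine = 64, sleep = 83, bmi = 63,
                  lipids = 68, glucose = 61, bp = 83)
  expect_equal(overall_cvh(s), 65)
  expect_equal(overall_cvh(s * 0), 0)
  expect_equal(overall_cvh(s * 0 + 100), 100)
  expect_true(is.na(overall_cvh(within(s, diet <- NA))))

  expect_equal(categorize(c(0, 49.9, 50, 79.9, 80, 100)),
               c("poor", "poor", "intermediate", "intermediate",
                 "high", "high"))
})

test_that("every scorer only ever emits its declared ladder values minus
          admissible deductions, never negative", {
  set.seed(77)
  d <- random_scorable_cohort(4000)
  sc <- score_cohort(d, diet_cutoffs = c(40, 50, 60, 75))
  tab <- scoring_tables()
  allowed <- function(pts, ded) sort(unique(c(pts, pmax(pts - ded, 0))))
  expect_true(all(sc$pa %in% tab$pa$points))
  expect_true(all(sc$sleep %in% tab$sleep$points))
  expect_true(all(sc$bmi %in% tab$bmi$points))
  expect_true(all(sc$diet %in% tab$diet_bands$points))
  expect_true(all(sc$nicotine %in% allowed(tab$nicotine_base, 20)))
  expect_true(all(sc$lipids %in% allowed(tab$lipids$points, 20)))
  expect_true(all(sc$bp %in%
                    allowed(c(tab$bp_sbp$points, tab$bp_dbp$points), 20)))
  expect_true(all(sc$glucose %in% c(100, 60, tab$glucose_hba1c$points)))
  expect_true(all(sc[, le8_components()] >= 0))
  expect_equal(sc$cvh, rowMeans(sc[, le8_components()]))
})

test_that("vectorized cohort scoring equals the per-record oracle", {
  set.seed(78)
  d <- random_scorable_cohort(2000)
  cuts <- c(40, 50, 60, 75)
  sc <- score_cohort(d, diet_cutoffs = cuts)
  for (i in sample(nrow(d), 300)) {
    want <- oracle_le8_record(d[i, ], sc$hei[i], cuts)
    got <- unlist(sc[i, le8_components()])
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 info = paste("record", i))
  }
})

test_that("scores respond monotonically to worsening inputs", {
  # higher BMI, non-HDL, BP, glucose never raise the score
  b <- seq(18, 45, by = 0.5)
  expect_true(all(diff(score_bmi(rep(100, length(b)), b)) <= 0))
  l <- seq(80, 260, by = 5)
  expect_true(all(diff(score_lipids(l, rep(FALSE, length(l)))) <= 0))
  s <- seq(95, 180, by = 1)
  expect_true(all(diff(score_bp(s, rep(60, length(s)),
                                rep(FALSE, length(s)))) <= 0))
  g <- seq(70, 125, by = 1)
  expect_true(all(diff(score_glucose(rep(FALSE, length(g)),
                                     rep(FALSE, length(g)), g,
                                     rep(NA_real_, length(g)))) <= 0))
  # more sleep up to 8 h never lowers the sleep score
  h <- seq(0, 8, by = 0.1)
  expect_true(all(diff(score_sleep(h)) >= 0))
})
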