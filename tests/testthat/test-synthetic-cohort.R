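# Synthetic cohort generator: determinism, ground-truth behavior,
# missingness calibration, weighting, and design-effect sanity.

test_that("the generator is reproducible and validates its configuration", {
  cfg <- sim_config(seed = 51, n_per_cycle = 300, cycles = c("c1", "c2"),
                    gt_n = 100)
  a <- generate_cohort(cfg, ground_truth = FALSE)$cohort
  b <- generate_cohort(cfg, ground_truth = FALSE)$cohort
  expect_identical(a, b)
  expect_error(sim_config(psus_per_stratum = 1), "psus_per_stratum")
  bad_demo <- default_demographics()
  bad_demo$race_pop["Other"] <- 0.5
  expect_error(sim_config(demographics = bad_demo), "probabilities")
  expect_error(sim_config(missingness = list(r1 = 1.2)), "missingness")
  d <- generate_cohort(sim_config(seed = 52, n_per_cycle = 200, gt_n = 50),
                       ground_truth = FALSE)$cohort
  expect_silent(validate_cohort(d))
})

test_that("zero trend slopes give exactly constant ground-truth means", {
  cfg <- sim_config(seed = 53, n_per_cycle = 50, gt_n = 4000,
                    missingness = list())
  gt <- generate_cohort(cfg, ground_truth = TRUE)$ground_truth
  m <- gt$component_means
  for (col in names(m)) expect_equal(diff(m[[col]]), rep(0, nrow(m) - 1))
})

test_that("calibrated BMI score trends move the ground truth by exactly the
          requested slope per cycle", {
  cfg <- sim_config(seed = 54, n_per_cycle = 50, gt_n = 2000,
                    score_trends = list(bmi = -0.6))
  gt <- generate_cohort(cfg, ground_truth = TRUE)$ground_truth
  expect_equal(diff(gt$component_means$bmi), rep(-0.6, 6), tolerance = 1e-9)
  expect_error(
    generate_cohort(sim_config(score_trends = list(sleep = 1)),
                    ground_truth = FALSE), "score_trends")
  expect_error(
    calibrate_bmi_locations(default_marginals()$bmi, -12, 7), "outside")
})

test_that("raw-scale trends shift the affected metric's ground truth in the
          right direction and leave others flat", {
  cfg <- sim_config(seed = 55, n_per_cycle = 50, gt_n = 5000,
                    trends = list(non_hdl_mgdl = 6))
  gt <- generate_cohort(cfg, ground_truth = TRUE)$ground_truth
  m <- gt$component_means
  expect_lt(m$lipids[7], m$lipids[1])     # higher non-HDL, lower score
  expect_equal(diff(m$sleep), rep(0, 6))  # untouched metrics stay constant
  expect_equal(diff(m$pa), rep(0, 6))
})

test_that("missingness injection hits the requested MCAR rates", {
  cfg <- sim_config(seed = 56, n_per_cycle = 500, cycles = "c1",
                    missingness = list(), gt_n = 50)
  d <- generate_cohort(cfg, ground_truth = FALSE)$cohort
  expect_identical(inject_missingness(d, list(sleep_hours = 0)), d)
  all_gone <- inject_missingness(d, list(sleep_hours = 1))
  expect_true(all(is.na(all_gone$sleep_hours)))

  set.seed(57)
  big <- d[rep(seq_len(nrow(d)), 20), ]   # n = 10,000
  hit <- inject_missingness(big, list(r1 = 0.2))
  frac <- mean(is.na(hit$r1_energy_kcal))
  expect_gt(frac, 0.18)                    # binomial 99% interval at n=1e4
  expect_lt(frac, 0.22)
  expect_true(all(is.na(hit$r1_total_veg) == is.na(hit$r1_energy_kcal)))
  expect_error(inject_missingness(d, list(nope = 0.1)), "unknown field")
})

test_that("weighted demographic composition matches the declared population
          mix despite oversampling", {
  cfg <- sim_config(seed = 58, n_per_cycle = 8000, cycles = "c1",
                    missingness = list(), gt_n = 50)
  d <- generate_cohort(cfg, ground_truth = FALSE)$cohort
  pop <- default_demographics()$race_pop
  for (grp in names(pop)) {
    w_frac <- sum(d$weight[d$race_ethnicity == grp]) / sum(d$weight)
    expect_equal(w_frac, unname(pop[grp]), tolerance = 0.035)
  }
  # oversampling is real: the raw fraction of NH-Black exceeds its
  # population share
  expect_gt(mean(d$race_ethnicity == "NH-Black"),
            unname(pop["NH-Black"]) + 0.05)
})

test_that("pipeline estimates converge to the ground truth on a large
          equal-ish sample", {
  cfg <- sim_config(seed = 59, n_per_cycle = 12000, cycles = "c1",
                    weight_dispersion = 0.05, missingness = list(),
                    gt_n = 2e5)
  g <- generate_cohort(cfg, ground_truth = TRUE)
  d <- apply_exclusion_cascade(g$cohort)$cohort
  sc <- score_cohort(d, diet_cutoffs = g$ground_truth$diet_cutoffs)
  des <- svy_design(sc)
  for (m in c("sleep", "bmi", "lipids", "glucose", "bp", "cvh")) {
    est <- svy_mean(des, m)
    truth <- g$ground_truth$component_means[[m]][1]
    mc_se <- sqrt(est$se^2 + (30 / sqrt(cfg$gt_n))^2)
    expect_lt(abs(est$estimate - truth), 3 * mc_se)
  }
})

test_that("larger weight dispersion never shrinks the average estimated SE", {
  mean_se <- function(disp) {
    ses <- vapply(1:8, function(r) {
      cfg <- sim_config(seed = 600 + r, n_per_cycle = 400, cycles = "c1",
                        weight_dispersion = disp, missingness = list(),
                        gt_n = 50)
      d <- generate_cohort(cfg, ground_truth = FALSE)$cohort
      d$bmi <- score_bmi(d$height_cm, d$weight_kg)
      svy_mean(svy_design(d), "bmi")$se
    }, numeric(1))
    mean(ses)
  }
  expect_gte(mean_se(0.9), mean_se(0.1))
})
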