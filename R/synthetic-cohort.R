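# Synthetic NHANES-like cohort generator with known ground truth.
#
# The generator draws a stratified two-PSU-per-stratum sample with unequal
# weights (inverse-probability weights for deliberately oversampled
# demographic groups times lognormal dispersion), realistic marginal
# distributions for all eight metric inputs, configurable linear time
# trends, and configurable missingness. Ground truth is recorded as the
# superpopulation mean of every LE8 component score per cycle.

#' Simulation configuration
#'
#' @param seed master seed; per-cycle streams are derived deterministically.
#' @param n_per_cycle examined persons per survey cycle.
#' @param cycles ordered cycle labels.
#' @param n_strata design strata per cycle.
#' @param psus_per_stratum sampled PSUs per stratum (must be >= 2 so that
#'   design-based variances exist).
#' @param weight_dispersion standard deviation of the lognormal noise
#'   multiplied onto the inverse-probability base weights.
#' @param marginals named list of marginal-distribution parameters (see
#'   \code{\link{default_marginals}}).
#' @param demographics demographic mix (see
#'   \code{\link{default_demographics}}).
#' @param trends named list of raw-measurement-scale linear slopes per cycle
#'   step, e.g. \code{list(sbp = 0.5, sleep_hours = 0.02)}; additive shifts
#'   on the named measurement.
#' @param score_trends named list of score-scale slopes per cycle step for
#'   single-measurement ladder metrics (currently \code{bmi}): the BMI
#'   location parameter is calibrated per cycle, through the closed-form
#'   expected ladder score of a lognormal BMI, so the superpopulation mean
#'   BMI score changes by exactly the requested amount per cycle.
#' @param missingness named list of missing-completely-at-random rates:
#'   field names of the cohort dictionary, or \code{"r1"}/\code{"r2"} for a
#'   whole recall, or \code{"recalls_both"} for both recalls jointly.
#' @param gt_n quasi-population size per cycle used for Monte-Carlo ground
#'   truth (common random numbers across cycles).
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1,
                       n_per_cycle = 1000,
                       cycles = c("2005-2006", "2007-2008", "2009-2010",
                                  "2011-2012", "2013-2014", "2015-2016",
                                  "2017-2018"),
                       n_strata = 15,
                       psus_per_stratum = 2,
                       weight_dispersion = 0.3,
                       marginals = default_marginals(),
                       demographics = default_demographics(),
                       trends = list(),
                       score_trends = list(),
                       missingness = default_missingness(),
                       gt_n = 1e6) {
  if (psus_per_stratum < 2)
    stop("sim_config: psus_per_stratum must be >= 2 for variance estimation")
  stopifnot(n_per_cycle > 0, n_strata > 0, weight_dispersion > 0)
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("sim_config: ", what, " probabilities must be in [0,1], sum 1")
  }
  for (nm in c("age_pop", "age_samp", "race_pop", "race_samp", "sex_pop",
               "sex_samp", "education", "marital"))
    check_probs(demographics[[nm]], nm)
  if (any(unlist(missingness) < 0) || any(unlist(missingness) > 1))
    stop("sim_config: missingness rates must be in [0,1]")
  structure(list(seed = seed, n_per_cycle = n_per_cycle, cycles = cycles,
                 n_strata = n_strata, psus_per_stratum = psus_per_stratum,
                 weight_dispersion = weight_dispersion,
                 marginals = marginals, demographics = demographics,
                 trends = trends, score_trends = score_trends,
                 missingness = missingness, gt_n = gt_n),
            class = "sim_config")
}

#' Default marginal-distribution parameters
#'
#' Location/scale (or probability) parameters approximating US adult
#' marginal distributions for every metric input; documented units. These
#' are superpopulation marginals — metric inputs are drawn independently of
#' demographics, which suffices because the package's validation targets the
#' scoring and estimation machinery, not joint realism.
#'
#' @return named list of parameter lists.
#' @export
default_marginals <- function() {
  list(
    bmi = list(meanlog = log(28.3), sdlog = 0.21, cluster_sd = 0.015,
               range = c(14, 70)),                      # kg/m^2, lognormal
    height = list(male = c(mean = 175.6, sd = 7.4),
                  female = c(mean = 162.0, sd = 6.9)),  # cm
    sleep_hours = list(mean = 7.05, sd = 1.25, cluster_sd = 0.10,
                       range = c(2, 14)),
    non_hdl = list(mean = 145, sd = 38, range = c(40, 400)),     # mg/dL
    sbp = list(mean = 121, sd = 15.5, cluster_sd = 1.5,
               range = c(80, 230)),                              # mmHg
    dbp = list(slope = 0.50, shift = 9, sd = 7, range = c(40, 150)),
    bp_reading_sd = 2.5,
    glucose = list(meanlog = log(99), sdlog = 0.17, range = c(50, 500)),
    hba1c = list(base = 5.55, per_mgdl = 0.012, sd = 0.35,
                 range = c(3.5, 16)),
    p_diabetes_history = 0.10, p_glucose_med_given_diab = 0.65,
    p_bp_med = 0.22, p_lipid_med = 0.15,
    smoking = c(never = 0.55, former_quit_ge5y = 0.19,
                former_quit_1to5y = 0.04, former_quit_lt1y = 0.02,
                current = 0.20),
    p_other_nicotine = 0.03, p_household_shs = 0.08,
    pa = list(p_inactive = 0.28, mod_meanlog = log(100), mod_sdlog = 1.0,
              p_no_vig = 0.55, vig_meanlog = log(60), vig_sdlog = 0.9),
    energy = list(meanlog = log(2000), sdlog = 0.28, range = c(500, 6000)),
    # typical densities per 1,000 kcal (or % of energy), lognormal sdlog
    diet_density = list(
      total_fruits = c(ml = log(0.50), sl = 0.60),
      whole_fruits = c(ml = log(0.25), sl = 0.70),
      total_veg = c(ml = log(0.75), sl = 0.45),
      greens_beans = c(ml = log(0.12), sl = 0.80),
      dairy = c(ml = log(0.80), sl = 0.55),
      whole_grains = c(ml = log(0.45), sl = 0.75),
      refined_grains = c(ml = log(3.0), sl = 0.35),
      total_protein = c(ml = log(3.3), sl = 0.30),
      seafood_plant_protein = c(ml = log(0.35), sl = 0.85),
      sodium_g = c(ml = log(1.70), sl = 0.25),
      added_sugars_pct = c(ml = log(13), sl = 0.45),
      satfat_pct = c(ml = log(11), sl = 0.30),
      mufa_pct = c(ml = log(12), sl = 0.25),
      pufa_pct = c(ml = log(8), sl = 0.30)),
    p_pregnant = 0.04, p_breastfeeding = 0.02, p_cvd_history = 0.06
  )
}

#' Default demographic mix
#'
#' Population category probabilities (what the weighted sample should
#' represent) and sampling probabilities (what is actually drawn;
#' minorities and older adults oversampled). Base weights are the
#' population-to-sampling probability ratios.
#'
#' @return named list of probability vectors.
#' @export
default_demographics <- function() {
  list(
    age_bands = rbind("20-39" = c(20, 39), "40-64" = c(40, 64),
                      "65-79" = c(65, 79), "80-85" = c(80, 85)),
    age_pop = c("20-39" = 0.36, "40-64" = 0.44, "65-79" = 0.13,
                "80-85" = 0.07),
    age_samp = c("20-39" = 0.31, "40-64" = 0.38, "65-79" = 0.24,
                 "80-85" = 0.07),
    sex_pop = c(male = 0.485, female = 0.515),
    sex_samp = c(male = 0.5, female = 0.5),
    race_pop = c("Hispanic" = 0.135, "NH-White" = 0.67, "NH-Black" = 0.105,
                 "Other" = 0.09),
    race_samp = c("Hispanic" = 0.26, "NH-White" = 0.37, "NH-Black" = 0.25,
                  "Other" = 0.12),
    education = c("<HS" = 0.13, "HS" = 0.22, "SomeCollege" = 0.32,
                  "CollegeGrad" = 0.33),
    marital = c(married = 0.56, div_sep_widowed = 0.16,
                unmarried_cohab = 0.28)
  )
}

#' Default missing-completely-at-random rates
#'
#' Both dietary recalls are jointly missing for 10% of persons (skipped the
#' dietary component altogether) and each recall is additionally missing
#' independently for 5.5%; laboratory and questionnaire fields have small
#' rates, so that the exclusion cascade has realistic work to do.
#'
#' @return named list of rates.
#' @export
default_missingness <- function() {
  list(recalls_both = 0.10, r1 = 0.055, r2 = 0.055,
       sleep_hours = 0.010, non_hdl_mgdl = 0.040,
       fasting_glucose_mgdl = 0.040, hba1c_pct = 0.020,
       moderate_pa_min_wk = 0.010, smoking_status = 0.005,
       education = 0.010, income_poverty_ratio = 0.050)
}

# Expected ladder score of a lognormal measurement with location meanlog and
# total scale sdlog: sum over ladder cells of points * cell probability.
ladder_mean_lognormal <- function(meanlog, sdlog, ladder) {
  b <- c(ladder$from, Inf)
  logb <- suppressWarnings(log(b))
  logb[b <= 0] <- -Inf
  p <- pnorm((logb[-1] - meanlog) / sdlog) -
    pnorm((logb[-length(logb)] - meanlog) / sdlog)
  sum(p * ladder$points)
}

# Calibrate per-cycle lognormal location parameters so the expected BMI
# ladder score declines by exactly `slope` per cycle step.
calibrate_bmi_locations <- function(marg, slope, n_cycles,
                                    tables = scoring_tables()) {
  sd_tot <- sqrt(marg$sdlog^2 + marg$cluster_sd^2)
  base <- ladder_mean_lognormal(marg$meanlog, sd_tot, tables$bmi)
  targets <- base + slope * (seq_len(n_cycles) - 1)
  if (any(targets < 0 | targets > 100))
    stop("score trend drives the expected BMI score outside [0, 100]")
  vapply(targets, function(tg) {
    uniroot(function(m) ladder_mean_lognormal(m, sd_tot, tables$bmi) - tg,
            interval = marg$meanlog + c(-2, 2), tol = 1e-12)$root
  }, numeric(1))
}

# Draw one cycle's worth of raw records (no design columns, equal weights).
# `shift(var)` gives the additive raw-scale trend shift for this cycle;
# bmi_meanlog overrides the BMI location (score-scale calibration).
draw_measurements <- function(n, marg, shifts = list(), bmi_meanlog = NULL,
                              cluster = NULL) {
  sh <- function(v) shifts[[v]] %||% 0
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  cl_eff <- function(nm, sd) {
    if (is.null(cluster) || sd == 0) return(numeric(n) + rnorm(n, 0, sd) * 0)
    u <- rnorm(length(unique(cluster)), 0, sd)
    u[match(cluster, unique(cluster))]
  }
  d <- data.frame(row.names = seq_len(n))

  ml <- (bmi_meanlog %||% marg$bmi$meanlog)
  bmi <- clamp(exp(rnorm(n, ml, marg$bmi$sdlog) +
                     cl_eff("bmi", marg$bmi$cluster_sd)) + sh("bmi"),
               marg$bmi$range)
  d$sleep_hours <- round(clamp(rnorm(n, marg$sleep_hours$mean,
                                     marg$sleep_hours$sd) +
                                 cl_eff("sleep", marg$sleep_hours$cluster_sd) +
                                 sh("sleep_hours"),
                               marg$sleep_hours$range), 1)
  d$non_hdl_mgdl <- round(clamp(rnorm(n, marg$non_hdl$mean,
                                      marg$non_hdl$sd) + sh("non_hdl_mgdl"),
                                marg$non_hdl$range))
  sbp <- clamp(rnorm(n, marg$sbp$mean, marg$sbp$sd) +
                 cl_eff("sbp", marg$sbp$cluster_sd) + sh("sbp"),
               marg$sbp$range)
  dbp <- clamp(marg$dbp$slope * sbp + marg$dbp$shift +
                 rnorm(n, 0, marg$dbp$sd) + sh("dbp"), marg$dbp$range)
  dbp <- pmin(dbp, sbp - 10)
  for (k in 1:3) {
    d[[paste0("sbp_", k)]] <- round(sbp + rnorm(n, 0, marg$bp_reading_sd))
    d[[paste0("dbp_", k)]] <- round(pmin(dbp + rnorm(n, 0,
                                                     marg$bp_reading_sd),
                                         d[[paste0("sbp_", k)]] - 5))
  }
  d$fasting_glucose_mgdl <- round(clamp(rlnorm(n, marg$glucose$meanlog,
                                               marg$glucose$sdlog) +
                                          sh("fasting_glucose_mgdl"),
                                        marg$glucose$range))
  d$hba1c_pct <- round(clamp(marg$hba1c$base + marg$hba1c$per_mgdl *
                               (d$fasting_glucose_mgdl - 100) +
                               rnorm(n, 0, marg$hba1c$sd) + sh("hba1c_pct"),
                             marg$hba1c$range), 1)
  d$diabetes_history <- runif(n) < marg$p_diabetes_history
  d$glucose_med <- ifelse(d$diabetes_history,
                          runif(n) < marg$p_glucose_med_given_diab,
                          runif(n) < 0.01)
  d$bp_med <- runif(n) < marg$p_bp_med
  d$lipid_med <- runif(n) < marg$p_lipid_med
  d$smoking_status <- sample(names(marg$smoking), n, TRUE, marg$smoking)
  d$other_nicotine_use <- runif(n) < marg$p_other_nicotine
  d$household_shs <- runif(n) < marg$p_household_shs
  active <- runif(n) >= marg$pa$p_inactive
  mod <- ifelse(active,
                round(rlnorm(n, marg$pa$mod_meanlog, marg$pa$mod_sdlog) /
                        5) * 5, 0)
  vig <- ifelse(active & runif(n) >= marg$pa$p_no_vig,
                round(rlnorm(n, marg$pa$vig_meanlog, marg$pa$vig_sdlog) /
                        5) * 5, 0)
  d$moderate_pa_min_wk <- pmax(mod + sh("moderate_pa_min_wk"), 0)
  d$vigorous_pa_min_wk <- pmax(vig + sh("vigorous_pa_min_wk"), 0)
  for (k in 1:2) {
    energy <- round(clamp(rlnorm(n, marg$energy$meanlog, marg$energy$sdlog),
                          marg$energy$range))
    d[[paste0("r", k, "_energy_kcal")]] <- energy
    dd <- marg$diet_density
    dens <- function(nm, shift_nm = nm)
      pmax(rlnorm(n, dd[[nm]]["ml"], dd[[nm]]["sl"]) + sh(shift_nm), 0)
    for (nm in c("total_fruits", "whole_fruits", "total_veg", "greens_beans",
                 "dairy", "whole_grains", "refined_grains", "total_protein",
                 "seafood_plant_protein"))
      d[[paste0("r", k, "_", nm)]] <- round(dens(nm) * energy / 1000, 3)
    d[[paste0("r", k, "_sodium_g")]] <- round(dens("sodium_g") * energy /
                                                1000, 3)
    d[[paste0("r", k, "_added_sugars_tsp")]] <-
      round(dens("added_sugars_pct") * energy / 100 / 16, 3)
    d[[paste0("r", k, "_satfat_g")]] <- round(dens("satfat_pct") * energy /
                                                100 / 9, 3)
    d[[paste0("r", k, "_mufa_g")]] <- round(dens("mufa_pct") * energy /
                                              100 / 9, 3)
    d[[paste0("r", k, "_pufa_g")]] <- round(dens("pufa_pct") * energy /
                                              100 / 9, 3)
  }
  attr(d, "bmi") <- bmi
  d
}

draw_demographics <- function(n, demo, marg, use_pop_mix = FALSE) {
  pick <- function(pop, samp) {
    pr <- if (use_pop_mix) pop else samp
    lab <- sample(names(pop), n, TRUE, pr)
    list(lab = lab, w = unname(pop[lab] / (if (use_pop_mix) pop else
      samp)[lab]))
  }
  age_b <- pick(demo$age_pop, demo$age_samp)
  sex <- pick(demo$sex_pop, demo$sex_samp)
  race <- pick(demo$race_pop, demo$race_samp)
  lims <- demo$age_bands[age_b$lab, , drop = FALSE]
  age <- floor(runif(n, lims[, 1], lims[, 2] + 1))
  d <- data.frame(
    age = pmin(age, lims[, 2]),
    sex = sex$lab,
    race_ethnicity = race$lab,
    education = sample(names(demo$education), n, TRUE, demo$education),
    marital = sample(names(demo$marital), n, TRUE, demo$marital),
    income_poverty_ratio = round(pmin(rlnorm(n, log(2.4), 0.8), 13), 2),
    stringsAsFactors = FALSE)
  fem_young <- d$sex == "female" & d$age < 45
  d$pregnant <- fem_young & runif(n) < marg$p_pregnant
  d$breastfeeding <- fem_young & !d$pregnant & runif(n) < marg$p_breastfeeding
  d$cvd_history <- runif(n) < marg$p_cvd_history
  d$base_weight <- age_b$w * sex$w * race$w
  d
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws \code{n_per_cycle} records for every cycle: demographics from the
#' sampling mix with inverse-probability base weights times lognormal
#' dispersion, a stratified design with \code{psus_per_stratum} PSUs per
#' stratum (small PSU-level random effects on BMI, blood pressure and sleep
#' create intra-cluster correlation), metric inputs from the configured
#' marginals with the configured trends applied, and MCAR missingness.
#'
#' @param config a \code{\link{sim_config}}.
#' @param ground_truth compute the ground-truth block (set FALSE to skip the
#'   quasi-population pass when only the sample is needed).
#' @return list with \code{cohort} (canonical cohort data.frame) and
#'   \code{ground_truth} (list: per-cycle superpopulation mean of each LE8
#'   component score and the overall score, plus injected slopes;
#'   NULL when not requested). Monte-Carlo ground truth uses common random
#'   numbers across cycles, so zero-trend configurations have exactly
#'   constant ground-truth means; BMI score-trend means are closed-form.
#' @export
generate_cohort <- function(config, ground_truth = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n_cyc <- length(config$cycles)
  bmi_ml <- NULL
  if (!is.null(config$score_trends$bmi))
    bmi_ml <- calibrate_bmi_locations(config$marginals$bmi,
                                      config$score_trends$bmi, n_cyc)
  unsupported <- setdiff(names(config$score_trends), "bmi")
  if (length(unsupported))
    stop("score_trends supported for: bmi (got ",
         paste(unsupported, collapse = ", "), ")")
  out <- vector("list", n_cyc)
  for (t in seq_len(n_cyc)) {
    set.seed(config$seed + 7919L * t)
    n <- config$n_per_cycle
    shifts <- lapply(config$trends, function(s) s * (t - 1))
    # balanced randomized allocation so every PSU is sampled (a 2-PSU
    # stratum with an empty PSU would make the design inestimable)
    n_cells <- config$n_strata * config$psus_per_stratum
    cell <- sample(rep_len(seq_len(n_cells), n))
    stratum <- (cell - 1L) %/% config$psus_per_stratum + 1L
    psu <- (cell - 1L) %% config$psus_per_stratum + 1L
    cl <- paste(stratum, psu)
    demo <- draw_demographics(n, config$demographics, config$marginals)
    meas <- draw_measurements(n, config$marginals, shifts,
                              bmi_meanlog = if (is.null(bmi_ml)) NULL else
                                bmi_ml[t],
                              cluster = cl)
    bmi <- attr(meas, "bmi")
    height <- ifelse(demo$sex == "male",
                     rnorm(n, config$marginals$height$male["mean"],
                           config$marginals$height$male["sd"]),
                     rnorm(n, config$marginals$height$female["mean"],
                           config$marginals$height$female["sd"]))
    d <- data.frame(id = sprintf("%s-%06d", config$cycles[t], seq_len(n)),
                    cycle = config$cycles[t],
                    stratum = sprintf("%s-%02d", config$cycles[t], stratum),
                    psu = as.character(psu),
                    weight = round(demo$base_weight *
                                     exp(rnorm(n, 0,
                                               config$weight_dispersion)), 6),
                    stringsAsFactors = FALSE)
    d <- cbind(d, demo[setdiff(names(demo), "base_weight")])
    d$height_cm <- round(height, 1)
    d$weight_kg <- round(bmi * (d$height_cm / 100)^2, 1)
    d <- cbind(d, meas)
    d <- inject_missingness(d, config$missingness)
    out[[t]] <- d
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  gt <- if (ground_truth) compute_ground_truth(config, bmi_ml) else NULL
  list(cohort = cohort, ground_truth = gt)
}

# Superpopulation per-cycle mean of every LE8 component score: a
# quasi-population of gt_n persons from the *population* demographic mix
# restricted to ages 20-79, equal weights, no missingness, scored with
# pooled-across-cycles diet cutoffs. Common random numbers across cycles.
compute_ground_truth <- function(config, bmi_ml = NULL,
                                 tables = scoring_tables(),
                                 standards = hei_standards()) {
  n_cyc <- length(config$cycles)
  gt_seed <- config$seed + 104729L
  demo_pop <- config$demographics
  keep <- setdiff(names(demo_pop$age_pop), "80-85")
  demo_pop$age_pop <- demo_pop$age_pop[keep] / sum(demo_pop$age_pop[keep])
  demo_pop$age_samp <- demo_pop$age_pop
  demo_pop$age_bands <- demo_pop$age_bands[keep, , drop = FALSE]
  comp <- le8_components()
  means <- matrix(NA_real_, n_cyc, length(comp) + 1,
                  dimnames = list(config$cycles, c(comp, "cvh")))
  heis <- vector("list", n_cyc)
  scored <- vector("list", n_cyc)
  for (t in seq_len(n_cyc)) {
    set.seed(gt_seed)           # common random numbers across cycles
    n <- config$gt_n
    shifts <- lapply(config$trends, function(s) s * (t - 1))
    demo <- draw_demographics(n, demo_pop, config$marginals,
                              use_pop_mix = TRUE)
    meas <- draw_measurements(n, config$marginals, shifts,
                              bmi_meanlog = if (is.null(bmi_ml)) NULL else
                                bmi_ml[t], cluster = NULL)
    bmi <- attr(meas, "bmi")
    s <- data.frame(
      pa = score_pa(meas$moderate_pa_min_wk, meas$vigorous_pa_min_wk,
                    tables$vigorous_multiplier, tables),
      nicotine = score_nicotine(meas$smoking_status, meas$other_nicotine_use,
                                meas$household_shs, tables = tables),
      sleep = score_sleep(meas$sleep_hours, tables),
      bmi = ladder_lookup(bmi, tables$bmi),
      lipids = score_lipids(meas$non_hdl_mgdl, meas$lipid_med, tables),
      glucose = score_glucose(meas$diabetes_history, meas$glucose_med,
                              meas$fasting_glucose_mgdl, meas$hba1c_pct,
                              tables))
    bp <- average_bp(as.matrix(meas[, paste0("sbp_", 1:3)]),
                     as.matrix(meas[, paste0("dbp_", 1:3)]))
    s$bp <- score_bp(bp$sbp, bp$dbp, meas$bp_med, tables)
    heis[[t]] <- person_hei(recall_frame(meas, 1), recall_frame(meas, 2),
                            min_recalls = 2, standards = standards)
    scored[[t]] <- s
  }
  cuts <- weighted_percentile(unlist(heis), rep(1, n_cyc * config$gt_n),
                              tables$diet_bands$pctl[-1])
  for (t in seq_len(n_cyc)) {
    s <- scored[[t]]
    s$diet <- score_diet(heis[[t]], cuts, tables)
    means[t, comp] <- colMeans(s[, comp])
    means[t, "cvh"] <- mean(overall_cvh(s))
  }
  if (!is.null(bmi_ml)) {
    sd_tot <- sqrt(config$marginals$bmi$sdlog^2 +
                     config$marginals$bmi$cluster_sd^2)
    means[, "bmi"] <- vapply(bmi_ml, ladder_mean_lognormal, numeric(1),
                             sdlog = sd_tot, ladder = tables$bmi)
  }
  list(component_means = as.data.frame(means),
       diet_cutoffs = cuts,
       injected_score_slopes = config$score_trends,
       injected_raw_slopes = config$trends,
       gt_n = config$gt_n)
}

#' Inject missing-completely-at-random values
#'
#' @param data cohort data.frame.
#' @param rates named list of rates in [0, 1]: a cohort column name, or
#'   \code{"r1"}/\code{"r2"} (all intake fields of that recall), or
#'   \code{"recalls_both"} (both recalls jointly).
#' @return the data.frame with values set to NA.
#' @export
inject_missingness <- function(data, rates) {
  if (any(unlist(rates) < 0) || any(unlist(rates) > 1))
    stop("inject_missingness: rates must be in [0,1]")
  n <- nrow(data)
  blank_recall <- function(d, k, mask) {
    for (f in recall_fields()) d[mask, paste0("r", k, "_", f)] <- NA_real_
    d
  }
  for (nm in names(rates)) {
    mask <- runif(n) < rates[[nm]]
    if (nm == "recalls_both") {
      data <- blank_recall(blank_recall(data, 1, mask), 2, mask)
    } else if (nm %in% c("r1", "r2")) {
      data <- blank_recall(data, as.integer(substr(nm, 2, 2)), mask)
    } else if (nm %in% names(data)) {
      data[mask, nm] <- NA
    } else {
      stop("inject_missingness: unknown field: ", nm)
    }
  }
  data
}

#' Write a generated cohort and its ground truth
#'
#' Writes the canonical cohort CSV and a ground-truth JSON sidecar.
#'
#' @param generated result of \code{\link{generate_cohort}}.
#' @param path CSV path (the sidecar gets extension \code{.truth.json}).
#' @export
write_generated_cohort <- function(generated, path) {
  write_cohort(generated$cohort, path)
  if (!is.null(generated$ground_truth))
    jsonlite::write_json(generated$ground_truth,
                         paste0(sub("\\.csv$", "", path), ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
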