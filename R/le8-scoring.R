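# Life's Essential 8: raw measurements -> eight 0-100 component scores,
# overall score (mean of the eight), and poor/intermediate/high categories.
#
# Every ladder lives in the scoring_tables() config so that algorithm
# revisions change data, not code. Scorers are vectorized and return NA for
# rows whose required inputs are missing.

#' LE8 scoring tables
#'
#' The points ladders, deduction amounts and conventions of the AHA Life's
#' Essential 8 scoring algorithm for adults, as an editable configuration
#' object. Each continuous ladder is given as parallel vectors of lower
#' bounds (\code{from}, inclusive) and points; intervals run to the next
#' bound (half-open).
#'
#' @return A named list with elements \code{pa}, \code{sleep}, \code{bmi},
#'   \code{lipids}, \code{bp_sbp}, \code{bp_dbp}, \code{glucose_no_diabetes},
#'   \code{glucose_hba1c}, \code{nicotine_base}, \code{diet_bands},
#'   \code{deductions} (secondhand smoke 20, BP treatment 20, lipid
#'   treatment 20), \code{vigorous_multiplier} (2) and category cut points.
#' @export
scoring_tables <- function() {
  list(
    # total activity minutes/week (moderate + multiplier * vigorous)
    pa = list(from = c(0, 1, 30, 60, 90, 120, 150),
              points = c(0, 20, 40, 60, 80, 90, 100)),
    # hours/day; non-monotone ladder handled by explicit intervals
    sleep = list(from = c(0, 4, 5, 6, 7, 9, 10),
                 points = c(0, 20, 40, 70, 100, 90, 40)),
    bmi = list(from = c(0, 25, 30, 35, 40),
               points = c(100, 70, 30, 15, 0)),
    lipids = list(from = c(0, 130, 160, 190, 220),
                  points = c(100, 60, 40, 20, 0)),
    bp_sbp = list(from = c(0, 120, 130, 140, 160),
                  points = c(100, 75, 50, 25, 0)),
    bp_dbp = list(from = c(0, 80, 90, 100),
                  points = c(100, 50, 25, 0)),
    glucose_no_diabetes = list(fbg = list(from = c(0, 100, 126),
                                          points = c(100, 60, NA)),
                               hba1c = list(from = c(0, 5.7, 6.5),
                                            points = c(100, 60, NA))),
    glucose_hba1c = list(from = c(0, 7, 8, 9, 10),
                         points = c(40, 30, 20, 10, 0)),
    nicotine_base = c(never = 100, former_quit_ge5y = 75,
                      former_quit_1to5y = 50, former_quit_lt1y = 25,
                      current = 0),
    # diet: HEI percentile bands (lower percentile bound -> points)
    diet_bands = list(pctl = c(0, 0.25, 0.50, 0.75, 0.95),
                      points = c(0, 25, 50, 80, 100)),
    deductions = c(shs = 20, bp_med = 20, lipid_med = 20),
    vigorous_multiplier = 2,
    categories = list(breaks = c(0, 50, 80), labels = c("poor",
                                                        "intermediate",
                                                        "high"))
  )
}

# Step-function lookup on a half-open ladder: value in [from[k], from[k+1])
# gets points[k]; below from[1] -> NA (out of declared range).
ladder_lookup <- function(x, ladder) {
  idx <- findInterval(x, ladder$from)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx) & idx >= 1
  out[ok] <- ladder$points[idx[ok]]
  out
}

#' Diet score from person-level HEI and percentile cutoffs
#'
#' HEI at or above the 95th-percentile cutoff scores 100; the 75th, 80; the
#' 50th, 50; the 25th, 25; below the 25th, 0. A value equal to a cutoff
#' qualifies for the higher band, so in a degenerate population where all HEI
#' are equal everyone scores 100.
#'
#' @param hei numeric vector of person-level HEI-2015 totals.
#' @param cutoffs named or ordered numeric vector of the 25th/50th/75th/95th
#'   weighted-percentile cutoffs of the reference population (see
#'   \code{\link{diet_percentile_cutoffs}}).
#' @param tables scoring tables.
#' @return integer-valued scores in \{0, 25, 50, 80, 100\}, NA for NA input.
#' @export
score_diet <- function(hei, cutoffs, tables = scoring_tables()) {
  bands <- tables$diet_bands
  stopifnot(length(cutoffs) == length(bands$pctl) - 1)
  score <- rep(NA_real_, length(hei))
  ok <- !is.na(hei)
  score[ok] <- bands$points[1]
  for (k in seq_along(cutoffs)) {
    score[ok & hei >= cutoffs[k]] <- bands$points[k + 1]
  }
  score
}

#' Weighted HEI percentile cutoffs for diet scoring
#'
#' @param hei person-level HEI totals of the reference population.
#' @param weights survey weights (same length).
#' @param tables scoring tables (defines which percentiles are needed).
#' @return numeric vector of cutoffs (25th, 50th, 75th, 95th by default).
#' @export
diet_percentile_cutoffs <- function(hei, weights, tables = scoring_tables()) {
  ok <- !is.na(hei) & !is.na(weights)
  p <- tables$diet_bands$pctl[-1]
  weighted_percentile(hei[ok], weights[ok], p)
}

#' Physical-activity score
#'
#' Total activity is moderate minutes plus \code{multiplier} times vigorous
#' minutes per week (vigorous minutes count double by AHA convention).
#'
#' @param moderate_min,vigorous_min minutes/week.
#' @param multiplier weight on vigorous minutes.
#' @param tables scoring tables.
#' @export
score_pa <- function(moderate_min, vigorous_min,
                     multiplier = scoring_tables()$vigorous_multiplier,
                     tables = scoring_tables()) {
  check_range(moderate_min, 0, Inf, "moderate_pa_min_wk")
  check_range(vigorous_min, 0, Inf, "vigorous_pa_min_wk")
  total <- moderate_min + multiplier * vigorous_min
  ladder_lookup(total, tables$pa)
}

#' Nicotine-exposure score
#'
#' Never users score 100; former users 75/50/25 by time since quitting; any
#' current inhaled-product use (combustible or e-cigarette/other inhaled
#' nicotine in the past 30 days) scores 0. Living with an indoor smoker
#' deducts 20 points from a positive base score (floor 0).
#'
#' @param smoking_status one of \code{"never"}, \code{"former_quit_ge5y"},
#'   \code{"former_quit_1to5y"}, \code{"former_quit_lt1y"}, \code{"current"}.
#' @param other_nicotine_use logical: other inhaled nicotine product, past 30
#'   days (treated as current use).
#' @param household_shs logical: secondhand smoke exposure in the household.
#' @param count_noninhaled if TRUE, \code{other_nicotine_use} is interpreted
#'   as including non-inhaled products and still zeroes the base score.
#'   Default TRUE is inert because the canonical field is inhaled-only.
#' @param tables scoring tables.
#' @export
score_nicotine <- function(smoking_status, other_nicotine_use, household_shs,
                           count_noninhaled = TRUE,
                           tables = scoring_tables()) {
  base <- unname(tables$nicotine_base[as.character(smoking_status)])
  # unknown other-product use only matters when it could lower a positive base
  base[is.na(other_nicotine_use) & (is.na(base) | base > 0)] <- NA_real_
  base[!is.na(other_nicotine_use) & other_nicotine_use] <- 0
  ded <- ifelse(!is.na(household_shs) & household_shs,
                tables$deductions[["shs"]], 0)
  ded[is.na(household_shs)] <- NA_real_
  out <- ifelse(base > 0, pmax(base - ded, 0), base)
  out
}

#' Sleep-health score
#'
#' @param sleep_hours usual hours of sleep per day.
#' @param tables scoring tables.
#' @export
score_sleep <- function(sleep_hours, tables = scoring_tables()) {
  check_range(sleep_hours, 0, 24, "sleep_hours", right_open = TRUE)
  ladder_lookup(sleep_hours, tables$sleep)
}

#' Body-mass-index score
#'
#' BMI is weight (kg) divided by height (m) squared.
#'
#' @param height_cm,weight_kg anthropometrics.
#' @param tables scoring tables.
#' @export
score_bmi <- function(height_cm, weight_kg, tables = scoring_tables()) {
  check_range(height_cm, 50, 272, "height_cm")
  check_range(weight_kg, 10, 700, "weight_kg")
  bmi <- weight_kg / (height_cm / 100)^2
  ladder_lookup(bmi, tables$bmi)
}

#' Blood-lipids score from non-HDL cholesterol
#'
#' @param non_hdl_mgdl non-HDL cholesterol (total minus HDL), mg/dL.
#' @param lipid_med logical: on lipid-lowering medication (deducts 20 from a
#'   positive base score).
#' @param tables scoring tables.
#' @export
score_lipids <- function(non_hdl_mgdl, lipid_med, tables = scoring_tables()) {
  check_range(non_hdl_mgdl, 0, Inf, "non_hdl_mgdl")
  base <- ladder_lookup(non_hdl_mgdl, tables$lipids)
  apply_deduction(base, lipid_med, tables$deductions[["lipid_med"]])
}

#' Blood-glucose score
#'
#' Persons without diabetes (no history, no glucose-lowering medication, and
#' glycemia below the diabetic range) are scored on fasting glucose — under
#' 100 mg/dL scores 100, 100-125 scores 60 — falling back to HbA1c (<5.7%
#' scores 100, 5.7-6.4 scores 60) when fasting glucose is missing. Persons
#' with diabetes (history, medication, FBG >= 126 mg/dL or HbA1c >= 6.5%) are
#' scored on HbA1c control: <7% scores 40, then 30/20/10 per percent, >= 10%
#' scores 0. With diabetes and a missing HbA1c the score is missing.
#'
#' @param diabetes_history logical.
#' @param glucose_med logical: insulin or oral hypoglycemic agents.
#' @param fasting_glucose_mgdl mg/dL, may be NA.
#' @param hba1c_pct percent, may be NA.
#' @param tables scoring tables.
#' @export
score_glucose <- function(diabetes_history, glucose_med, fasting_glucose_mgdl,
                          hba1c_pct, tables = scoring_tables()) {
  check_range(fasting_glucose_mgdl, 10, 1500, "fasting_glucose_mgdl")
  check_range(hba1c_pct, 2, 25, "hba1c_pct")
  n <- length(diabetes_history)
  fbg_band <- tables$glucose_no_diabetes$fbg
  a1c_band <- tables$glucose_no_diabetes$hba1c
  diab_fbg_cut <- fbg_band$from[length(fbg_band$from)]    # 126
  diab_a1c_cut <- a1c_band$from[length(a1c_band$from)]    # 6.5
  diabetic <- (!is.na(diabetes_history) & diabetes_history) |
    (!is.na(glucose_med) & glucose_med) |
    (!is.na(fasting_glucose_mgdl) & fasting_glucose_mgdl >= diab_fbg_cut) |
    (!is.na(hba1c_pct) & hba1c_pct >= diab_a1c_cut)
  # flags missing AND no glycemia in diabetic range -> cannot rule diabetes out
  flags_na <- is.na(diabetes_history) | is.na(glucose_med)

  out <- rep(NA_real_, n)
  nd <- !diabetic & !flags_na
  use_fbg <- nd & !is.na(fasting_glucose_mgdl)
  out[use_fbg] <- ladder_lookup(fasting_glucose_mgdl[use_fbg], fbg_band)
  use_a1c <- nd & is.na(fasting_glucose_mgdl) & !is.na(hba1c_pct)
  out[use_a1c] <- ladder_lookup(hba1c_pct[use_a1c], a1c_band)
  dd <- diabetic & !is.na(hba1c_pct)
  out[dd] <- ladder_lookup(hba1c_pct[dd], tables$glucose_hba1c)
  out
}

#' Blood-pressure averaging rule
#'
#' With 3 readings the average of the 2nd and 3rd is used; with 2 readings,
#' the average of the 1st and 2nd; with 1 reading, that reading.
#'
#' @param sbp_readings,dbp_readings numeric matrices (rows = persons, up to 3
#'   columns, trailing NAs for absent readings) or vectors for one person.
#' @return list with numeric vectors \code{sbp} and \code{dbp}.
#' @export
#' @examples
#' average_bp(c(130, 120, 110), c(85, 80, 75))  # 115 / 77.5
average_bp <- function(sbp_readings, dbp_readings) {
  if (is.null(dim(sbp_readings))) sbp_readings <- matrix(sbp_readings, nrow = 1)
  if (is.null(dim(dbp_readings))) dbp_readings <- matrix(dbp_readings, nrow = 1)
  avg_one <- function(m) {
    n_read <- rowSums(!is.na(m))
    out <- rep(NA_real_, nrow(m))
    out[n_read == 1] <- m[n_read == 1, 1]
    out[n_read == 2] <- rowMeans(m[n_read == 2, 1:2, drop = FALSE])
    out[n_read >= 3] <- rowMeans(m[n_read >= 3, 2:3, drop = FALSE])
    out
  }
  list(sbp = avg_one(sbp_readings), dbp = avg_one(dbp_readings))
}

#' Blood-pressure score
#'
#' The stage is determined by the worse of the systolic and diastolic
#' readings; antihypertensive treatment deducts 20 points from a positive
#' base score.
#'
#' @param sbp,dbp averaged readings, mmHg (see \code{\link{average_bp}}).
#' @param bp_med logical.
#' @param tables scoring tables.
#' @export
score_bp <- function(sbp, dbp, bp_med, tables = scoring_tables()) {
  check_range(sbp, 40, 350, "sbp")
  check_range(dbp, 10, 250, "dbp")
  if (any(!is.na(sbp) & !is.na(dbp) & dbp >= sbp))
    stop("score_bp: diastolic must be below systolic")
  base <- pmin(ladder_lookup(sbp, tables$bp_sbp),
               ladder_lookup(dbp, tables$bp_dbp))
  apply_deduction(base, bp_med, tables$deductions[["bp_med"]])
}

apply_deduction <- function(base, flag, amount) {
  ded <- ifelse(!is.na(flag) & flag, amount, 0)
  ded[is.na(flag)] <- NA_real_
  ifelse(base > 0, pmax(base - ded, 0), base)
}

#' Overall cardiovascular-health score
#'
#' The arithmetic mean of the eight component scores; missing if any
#' component is missing.
#'
#' @param scores data.frame or matrix with the eight component-score columns
#'   \code{diet}, \code{pa}, \code{nicotine}, \code{sleep}, \code{bmi},
#'   \code{lipids}, \code{glucose}, \code{bp}.
#' @export
overall_cvh <- function(scores) {
  comp <- le8_components()
  m <- as.matrix(as.data.frame(scores)[, comp])
  rowMeans(m)
}

#' @rdname overall_cvh
#' @export
le8_components <- function() {
  c("diet", "pa", "nicotine", "sleep", "bmi", "lipids", "glucose", "bp")
}

#' CVH category from a 0-100 score
#'
#' Poor is 0 to <50, intermediate 50 to <80, high 80 to 100.
#'
#' @param score numeric vector in [0, 100].
#' @param tables scoring tables.
#' @return character vector in \code{c("poor", "intermediate", "high")}.
#' @export
categorize <- function(score, tables = scoring_tables()) {
  check_range(score, 0, 100, "score")
  cats <- tables$categories
  cats$labels[findInterval(score, cats$breaks)]
}

#' Score a cohort table
#'
#' Computes person-level HEI, the diet percentile cutoffs over the chosen
#' reference population, all eight LE8 component scores, the overall score,
#' and categories, for a cohort table in the canonical column dictionary.
#'
#' @param data cohort data.frame (see \code{\link{cohort_dictionary}}).
#' @param tables scoring tables.
#' @param standards HEI standards.
#' @param diet_min_recalls recalls required for a non-missing diet score.
#' @param diet_ref \code{"pooled"} (default): percentile cutoffs from the
#'   whole (weighted) table; \code{"cycle"}: per-cycle cutoffs.
#' @param diet_cutoffs optional fixed cutoffs (overrides \code{diet_ref}).
#' @param hei_method passed to \code{\link{person_hei}}.
#' @return the input data.frame with added columns \code{hei}, the eight
#'   component scores, \code{cvh} (overall) and \code{cvh_category}.
#' @export
score_cohort <- function(data, tables = scoring_tables(),
                         standards = hei_standards(),
                         diet_min_recalls = 2,
                         diet_ref = c("pooled", "cycle"),
                         diet_cutoffs = NULL,
                         hei_method = c("mean_of_totals", "pooled")) {
  diet_ref <- match.arg(diet_ref)
  hei_method <- match.arg(hei_method)
  r1 <- recall_frame(data, 1)
  r2 <- recall_frame(data, 2)
  data$hei <- person_hei(r1, r2, min_recalls = diet_min_recalls,
                         method = hei_method, standards = standards)
  if (is.null(diet_cutoffs)) {
    if (diet_ref == "pooled") {
      cuts <- diet_percentile_cutoffs(data$hei, data$weight, tables)
      data$diet <- score_diet(data$hei, cuts, tables)
    } else {
      data$diet <- NA_real_
      for (cy in unique(data$cycle)) {
        i <- data$cycle == cy
        cuts <- diet_percentile_cutoffs(data$hei[i], data$weight[i], tables)
        data$diet[i] <- score_diet(data$hei[i], cuts, tables)
      }
    }
  } else {
    data$diet <- score_diet(data$hei, diet_cutoffs, tables)
  }
  data$pa <- score_pa(data$moderate_pa_min_wk, data$vigorous_pa_min_wk,
                      tables$vigorous_multiplier, tables)
  data$nicotine <- score_nicotine(data$smoking_status, data$other_nicotine_use,
                                  data$household_shs, tables = tables)
  data$sleep <- score_sleep(data$sleep_hours, tables)
  data$bmi_score <- score_bmi(data$height_cm, data$weight_kg, tables)
  data$lipids <- score_lipids(data$non_hdl_mgdl, data$lipid_med, tables)
  data$glucose <- score_glucose(data$diabetes_history, data$glucose_med,
                                data$fasting_glucose_mgdl, data$hba1c_pct,
                                tables)
  bp <- average_bp(as.matrix(data[, paste0("sbp_", 1:3)]),
                   as.matrix(data[, paste0("dbp_", 1:3)]))
  data$bp <- score_bp(bp$sbp, bp$dbp, data$bp_med, tables)
  # `bmi` column name is taken by the scored component in the result table
  data$bmi <- data$bmi_score
  data$bmi_score <- NULL
  data$cvh <- overall_cvh(data)
  data$cvh_category <- ifelse(is.na(data$cvh), NA_character_,
                              categorize(pmin(data$cvh, 100), tables))
  data
}

# Extract the recall-k intake columns of a cohort table as a plain frame.
recall_frame <- function(data, k) {
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (f in recall_fields()) {
    col <- paste0("r", k, "_", f)
    out[[f]] <- if (col %in% names(data)) data[[col]] else NA_real_
  }
  out
}

check_range <- function(x, lo, hi, what, right_open = FALSE) {
  bad <- !is.na(x) & (x < lo | if (right_open) x >= hi else x > hi)
  if (any(bad))
    stop(sprintf("%s out of physical range [%g, %g%s: e.g. %g", what, lo, hi,
                 if (right_open) ")" else "]", x[which(bad)[1]]))
  invisible(x)
}
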