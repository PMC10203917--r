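# Analytic-sample exclusion cascade and its flow accounting.

#' Cohort exclusion flow
#'
#' Ordered record of the exclusion stages applied to an initial sample: each
#' stage has a label, the number excluded at that stage, and the number
#' remaining afterwards. Remaining counts are recomputed from the excluded
#' counts, so the conservation identity
#' \eqn{n_0 - \sum_k e_k = n_\mathrm{final}} holds by construction and is
#' re-checked.
#'
#' @param initial initial sample size.
#' @param labels character vector of stage labels.
#' @param excluded integer vector of per-stage exclusion counts.
#' @return object of class \code{cohort_flow}: data.frame \code{stages}
#'   (label, n_excluded, n_remaining) plus \code{initial} and \code{final}.
#' @export
#' @examples
#' cohort_flow(39749, c("age >79", "missing CVH metric",
#'                      "missing demographics", "pregnant", "breastfeeding",
#'                      "CVD history"),
#'             c(2776, 10355, 2037, 481, 198, 2235))
cohort_flow <- function(initial, labels, excluded) {
  stopifnot(length(labels) == length(excluded))
  if (any(excluded < 0)) stop("cohort_flow: negative exclusion count")
  remaining <- initial - cumsum(excluded)
  if (any(remaining < 0)) stop("cohort_flow: more excluded than available")
  out <- list(initial = as.integer(initial),
              stages = data.frame(label = as.character(labels),
                                  n_excluded = as.integer(excluded),
                                  n_remaining = as.integer(remaining),
                                  stringsAsFactors = FALSE),
              final = as.integer(if (length(remaining))
                remaining[length(remaining)] else initial))
  stopifnot(out$initial - sum(out$stages$n_excluded) == out$final)
  class(out) <- "cohort_flow"
  out
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat(sprintf("Initial sample: %d\n", x$initial))
  for (k in seq_len(nrow(x$stages)))
    cat(sprintf("  - %-36s excluded %6d -> remaining %6d\n",
                x$stages$label[k], x$stages$n_excluded[k],
                x$stages$n_remaining[k]))
  cat(sprintf("Analyzed sample: %d\n", x$final))
  invisible(x)
}

#' Default exclusion rules
#'
#' The ordered predicate list of the analytic-sample cascade for an
#' NHANES-style adult examination sample: (1) age above 79; (2) missing any
#' input of the eight CVH metrics — operationally, any of the eight scorers
#' (diet requiring \code{diet_min_recalls} usable recalls) would return
#' missing; (3) missing demographics (sex, race/ethnicity, education,
#' marital status, income-poverty ratio); (4) pregnancy; (5) breastfeeding;
#' (6) self-reported CVD history. Each record is excluded at the first
#' failing rule only, so stage counts are sequential and mutually exclusive.
#'
#' @param diet_min_recalls recalls required for the diet metric (2 for the
#'   primary analysis, 1 for the one-recall sensitivity analysis).
#' @param tables,standards scoring configuration passed to the scorers.
#' @return named list of predicate functions \code{function(data)} returning
#'   a logical exclusion mask.
#' @export
default_exclusion_rules <- function(diet_min_recalls = 2,
                                    tables = scoring_tables(),
                                    standards = hei_standards()) {
  list(
    "age >79 years" = function(d) !is.na(d$age) & d$age > 79,
    "missing CVH metric" = function(d) missing_cvh_metric(d, diet_min_recalls,
                                                          tables, standards),
    "missing demographics" = function(d)
      is.na(d$sex) | is.na(d$race_ethnicity) | is.na(d$education) |
      is.na(d$marital) | is.na(d$income_poverty_ratio),
    "pregnant" = function(d) !is.na(d$pregnant) & d$pregnant,
    "breastfeeding" = function(d) !is.na(d$breastfeeding) & d$breastfeeding,
    "CVD history" = function(d) !is.na(d$cvd_history) & d$cvd_history
  )
}

# A person is missing a CVH metric when any of the eight scorers cannot
# produce a score from their inputs (diet: fewer than min_recalls usable
# recalls; the percentile step never creates missingness).
missing_cvh_metric <- function(d, diet_min_recalls = 2,
                               tables = scoring_tables(),
                               standards = hei_standards()) {
  hei <- person_hei(recall_frame(d, 1), recall_frame(d, 2),
                    min_recalls = diet_min_recalls, standards = standards)
  pa <- score_pa(d$moderate_pa_min_wk, d$vigorous_pa_min_wk,
                 tables$vigorous_multiplier, tables)
  nic <- score_nicotine(d$smoking_status, d$other_nicotine_use,
                        d$household_shs, tables = tables)
  slp <- score_sleep(d$sleep_hours, tables)
  bmi <- score_bmi(d$height_cm, d$weight_kg, tables)
  lip <- score_lipids(d$non_hdl_mgdl, d$lipid_med, tables)
  glu <- score_glucose(d$diabetes_history, d$glucose_med,
                       d$fasting_glucose_mgdl, d$hba1c_pct, tables)
  bp <- average_bp(as.matrix(d[, paste0("sbp_", 1:3)]),
                   as.matrix(d[, paste0("dbp_", 1:3)]))
  bps <- score_bp(bp$sbp, bp$dbp, d$bp_med, tables)
  is.na(hei) | is.na(pa) | is.na(nic) | is.na(slp) | is.na(bmi) |
    is.na(lip) | is.na(glu) | is.na(bps)
}

#' Apply the exclusion cascade
#'
#' Applies an ordered list of exclusion predicates; each record is excluded
#' at the first rule it fails, so the per-stage counts are sequential and
#' mutually exclusive and sum (with the final count) to the initial count.
#'
#' @param data cohort data.frame.
#' @param rules named list of predicate functions (see
#'   \code{\link{default_exclusion_rules}}).
#' @return list with \code{cohort} (the retained records) and \code{flow}
#'   (a \code{\link{cohort_flow}}).
#' @export
apply_exclusion_cascade <- function(data, rules = default_exclusion_rules()) {
  alive <- rep(TRUE, nrow(data))
  excluded <- integer(length(rules))
  for (k in seq_along(rules)) {
    if (any(alive)) {
      hit <- rep(FALSE, nrow(data))
      hit[alive] <- rules[[k]](data[alive, , drop = FALSE])
      hit[is.na(hit)] <- FALSE
      excluded[k] <- sum(hit & alive)
      alive <- alive & !hit
    }
  }
  list(cohort = data[alive, , drop = FALSE],
       flow = cohort_flow(nrow(data), names(rules), excluded))
}

#' Summarize a cohort flow
#'
#' @param flow a \code{\link{cohort_flow}}.
#' @param format \code{"json"} for a machine-readable JSON string,
#'   \code{"text"} for the human-readable rendering.
#' @return character scalar.
#' @export
summarize_flow <- function(flow, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "text")
    return(paste(utils::capture.output(print(flow)), collapse = "\n"))
  jsonlite::toJSON(list(initial = flow$initial, stages = flow$stages,
                        final = flow$final),
                   auto_unbox = TRUE, digits = NA)
}
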