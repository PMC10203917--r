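# Canonical person-level cohort table: column dictionary, CSV round trip,
# and a SAS-transport (XPT) reader with a name-mapping layer for real
# survey files.

#' Canonical cohort column dictionary
#'
#' One row per column of the canonical person-level cohort table: identifier,
#' survey-design variables, demographics, behavioral and clinical
#' measurements (three seated BP readings), and the intake fields of two
#' 24-hour dietary recalls (prefixes \code{r1_}/\code{r2_}). Missing values
#' are explicit \code{NA}s — refusal/don't-know sentinel codes must be
#' mapped to \code{NA} by the translation layer, never carried as numbers.
#'
#' @return data.frame with columns \code{name}, \code{type} (\code{numeric},
#'   \code{character}, \code{logical}), \code{required} (mandatory for
#'   loading).
#' @export
cohort_dictionary <- function() {
  num <- function(n, req = FALSE) data.frame(name = n, type = "numeric",
                                             required = req)
  chr <- function(n, req = FALSE) data.frame(name = n, type = "character",
                                             required = req)
  lgl <- function(n) data.frame(name = n, type = "logical", required = FALSE)
  rbind(
    chr("id", TRUE), chr("cycle", TRUE), chr("stratum", TRUE),
    chr("psu", TRUE), num("weight", TRUE),
    num("age", TRUE), chr("sex", TRUE), chr("race_ethnicity"),
    chr("education"), chr("marital"), num("income_poverty_ratio"),
    lgl("pregnant"), lgl("breastfeeding"), lgl("cvd_history"),
    num("moderate_pa_min_wk"), num("vigorous_pa_min_wk"),
    chr("smoking_status"), lgl("other_nicotine_use"), lgl("household_shs"),
    num("sleep_hours"),
    num("height_cm"), num("weight_kg"),
    num("sbp_1"), num("sbp_2"), num("sbp_3"),
    num("dbp_1"), num("dbp_2"), num("dbp_3"),
    lgl("bp_med"), num("non_hdl_mgdl"), lgl("lipid_med"),
    num("fasting_glucose_mgdl"), num("hba1c_pct"),
    lgl("diabetes_history"), lgl("glucose_med"),
    do.call(rbind, lapply(1:2, function(k)
      num(paste0("r", k, "_", recall_fields()))))
  )
}

#' Category sets of the canonical dictionary
#'
#' @return named list of the admissible levels of each categorical column.
#' @export
cohort_levels <- function() {
  list(
    sex = c("male", "female"),
    race_ethnicity = c("Hispanic", "NH-White", "NH-Black", "Other"),
    education = c("<HS", "HS", "SomeCollege", "CollegeGrad"),
    marital = c("married", "div_sep_widowed", "unmarried_cohab"),
    smoking_status = c("never", "former_quit_ge5y", "former_quit_1to5y",
                       "former_quit_lt1y", "current"),
    income_category = c("<1.30", "1.30-2.99", ">=3.00")
  )
}

#' Income-to-poverty-ratio category
#'
#' Low (<1.30), middle (1.30-2.99), high (>=3.00).
#'
#' @param ratio family income divided by the federal poverty threshold.
#' @export
income_category <- function(ratio) {
  lev <- cohort_levels()$income_category
  out <- rep(NA_character_, length(ratio))
  out[!is.na(ratio) & ratio < 1.3] <- lev[1]
  out[!is.na(ratio) & ratio >= 1.3 & ratio < 3] <- lev[2]
  out[!is.na(ratio) & ratio >= 3] <- lev[3]
  out
}

#' Read a cohort table
#'
#' Reads the canonical delimited (CSV, UTF-8, header) cohort format, or a
#' SAS transport (XPT) file with a name map translating source variable
#' names to the canonical dictionary. Unknown columns are dropped; optional
#' dictionary columns that are absent are created as missing. Malformed
#' numeric fields become \code{NA} with a per-row warning.
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"xpt"}.
#' @param name_map for XPT (or non-canonical CSV) files: a data.frame with
#'   columns \code{from} (source name) and \code{to} (canonical name).
#' @return data.frame in the canonical dictionary (one row per person).
#' @export
read_cohort <- function(path, format = c("csv", "xpt"), name_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_cohort: no such file: ", path)
  raw <- switch(format,
    csv = read.csv(path, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE),
    xpt = foreign::read.xport(path))
  if (!is.null(name_map)) {
    stopifnot(all(c("from", "to") %in% names(name_map)))
    hit <- match(names(raw), name_map$from)
    names(raw)[!is.na(hit)] <- name_map$to[hit[!is.na(hit)]]
  }
  dict <- cohort_dictionary()
  missing_req <- setdiff(dict$name[dict$required], names(raw))
  if (length(missing_req))
    stop("read_cohort: missing mandatory column(s): ",
         paste(missing_req, collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (k in seq_len(nrow(dict))) {
    nm <- dict$name[k]
    if (!nm %in% names(raw)) {
      out[[nm]] <- switch(dict$type[k], numeric = NA_real_,
                          character = NA_character_, logical = NA)
      next
    }
    col <- raw[[nm]]
    if (dict$type[k] == "numeric") {
      was_na <- is.na(col) | (is.character(col) & trimws(col) == "")
      val <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(val) & !was_na)
      if (length(bad))
        warning(sprintf("column '%s': malformed numeric in row(s) %s; set to NA",
                        nm, paste(utils::head(bad, 5), collapse = ", ")))
      out[[nm]] <- val
    } else if (dict$type[k] == "logical") {
      out[[nm]] <- parse_logical(col)
    } else {
      val <- as.character(col)
      val[!is.na(val) & trimws(val) == ""] <- NA_character_
      out[[nm]] <- val
    }
  }
  if (anyDuplicated(out$id))
    stop("read_cohort: duplicate person ids")
  out
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

#' Write a cohort table as canonical CSV
#'
#' @param data cohort data.frame.
#' @param path output path.
#' @export
write_cohort <- function(data, path) {
  dict <- cohort_dictionary()
  cols <- intersect(dict$name, names(data))
  write.csv(data[, cols, drop = FALSE], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort table against the dictionary invariants
#'
#' Checks required columns, positive weights, admissible category levels,
#' non-negative amounts, sleep below 24 h, and per-reading SBP > DBP.
#'
#' @param data cohort data.frame.
#' @return invisibly TRUE; stops with an informative message otherwise.
#' @export
validate_cohort <- function(data) {
  dict <- cohort_dictionary()
  miss <- setdiff(dict$name[dict$required], names(data))
  if (length(miss))
    stop("validate_cohort: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(data$id)) stop("validate_cohort: duplicate ids")
  if (any(is.na(data$weight) | data$weight <= 0))
    stop("validate_cohort: weights must be positive")
  lev <- cohort_levels()
  for (nm in intersect(names(lev), names(data))) {
    bad <- !is.na(data[[nm]]) & !data[[nm]] %in% lev[[nm]]
    if (any(bad))
      stop(sprintf("validate_cohort: invalid %s level(s): %s", nm,
                   paste(unique(data[[nm]][bad]), collapse = ", ")))
  }
  if (any(!is.na(data$sleep_hours) & data$sleep_hours >= 24))
    stop("validate_cohort: sleep_hours must be < 24")
  if (any(!is.na(data$income_poverty_ratio) & data$income_poverty_ratio < 0))
    stop("validate_cohort: income_poverty_ratio must be >= 0")
  for (k in 1:3) {
    s <- data[[paste0("sbp_", k)]]; d <- data[[paste0("dbp_", k)]]
    if (any(!is.na(s) & !is.na(d) & s <= d))
      stop("validate_cohort: SBP must exceed DBP in reading ", k)
  }
  invisible(TRUE)
}
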