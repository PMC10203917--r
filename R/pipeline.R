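# Orchestration: load/simulate -> exclude -> score -> estimate -> trend ->
# emit tables, as one configured, logged, reproducible run.

#' Pipeline run configuration
#'
#' @param input path of a canonical cohort CSV, or NULL to simulate.
#' @param simulation a \code{\link{sim_config}} (used when \code{input} is
#'   NULL).
#' @param diet_min_recalls recalls required for the diet metric (2 primary,
#'   1 sensitivity).
#' @param diet_ref diet percentile reference population: \code{"pooled"}
#'   (all analyzed cycles, default) or \code{"cycle"}.
#' @param vigorous_multiplier weight of vigorous activity minutes.
#' @param subgroups stratifiers for subgroup tables, drawn from
#'   \code{c("sex", "age_group", "race_ethnicity", "education", "marital",
#'   "income_category")}.
#' @param covariates adjustment covariates of the trend regression.
#' @param std_pop standard population for direct age standardization.
#' @param age_bands reporting band scheme (defaults to the standard
#'   population's three bands).
#' @param seed seed for any simulation randomness.
#' @param lonely_psu singleton-PSU policy (see \code{\link{svy_design}}).
#' @param out_dir output directory for \code{\link{emit_tables}} (NULL: do
#'   not write).
#' @return a \code{run_config} list.
#' @export
run_config <- function(input = NULL, simulation = sim_config(),
                       diet_min_recalls = 2,
                       diet_ref = c("pooled", "cycle"),
                       vigorous_multiplier = 2,
                       subgroups = c("sex", "age_group", "race_ethnicity",
                                     "education", "marital",
                                     "income_category"),
                       covariates = c("sex", "age_group", "race_ethnicity",
                                      "education", "marital",
                                      "income_category"),
                       std_pop = std_pop_us2018(),
                       age_bands = NULL,
                       seed = NULL,
                       lonely_psu = "fail",
                       out_dir = NULL) {
  diet_ref <- match.arg(diet_ref)
  ok_groups <- c("sex", "age_group", "race_ethnicity", "education",
                 "marital", "income_category")
  bad <- setdiff(subgroups, ok_groups)
  if (length(bad))
    stop("run_config: unknown subgroup(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) simulation$seed <- seed
  structure(list(input = input, simulation = simulation,
                 diet_min_recalls = diet_min_recalls, diet_ref = diet_ref,
                 vigorous_multiplier = vigorous_multiplier,
                 subgroups = subgroups, covariates = covariates,
                 std_pop = std_pop, age_bands = age_bands,
                 lonely_psu = lonely_psu, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Load (or simulate) the cohort, apply the exclusion cascade, score,
#' estimate crude and age-standardized per-cycle means of the overall score
#' and all eight components (overall and within each configured subgroup),
#' tabulate age-standardized category distributions, fit covariate-adjusted
#' linear trends, and test demographic homogeneity across cycles.
#'
#' @param config a \code{\link{run_config}}.
#' @param log_fn function receiving structured log records (a named list);
#'   default collects them into the report.
#' @return a \code{run_report}: list with \code{flow}, \code{estimates}
#'   (data.frame: cycle x subgroup x metric, crude and standardized),
#'   \code{categories} (age-standardized category proportions per cycle and
#'   metric), \code{trends} (data.frame of per-metric slope/se/p),
#'   \code{homogeneity} (chi-square results per demographic), and a
#'   \code{provenance} block (config hash, seed, package version).
#' @export
run_pipeline <- function(config, log_fn = NULL) {
  logs <- list()
  log1 <- function(...) {
    rec <- list(...)
    if (is.null(log_fn)) logs[[length(logs) + 1]] <<- rec else log_fn(rec)
  }
  tables <- scoring_tables()
  tables$vigorous_multiplier <- config$vigorous_multiplier

  if (!is.null(config$input)) {
    cohort <- read_cohort(config$input)
    log1(stage = "load", n = nrow(cohort), source = config$input)
  } else {
    gen <- generate_cohort(config$simulation, ground_truth = FALSE)
    cohort <- gen$cohort
    log1(stage = "simulate", n = nrow(cohort),
         seed = config$simulation$seed)
  }
  validate_cohort(cohort)

  rules <- default_exclusion_rules(config$diet_min_recalls, tables)
  excl <- apply_exclusion_cascade(cohort, rules)
  for (k in seq_len(nrow(excl$flow$stages)))
    log1(stage = "exclusion", rule = excl$flow$stages$label[k],
         excluded = excl$flow$stages$n_excluded[k],
         remaining = excl$flow$stages$n_remaining[k])
  data <- excl$cohort

  data <- score_cohort(data, tables, diet_min_recalls = config$diet_min_recalls,
                       diet_ref = config$diet_ref)
  data$age_group <- age_band(data$age, config$std_pop)
  data$income_category <- income_category(data$income_poverty_ratio)
  log1(stage = "score", n = nrow(data))

  design <- svy_design(data, lonely_psu = config$lonely_psu)
  metrics <- c("cvh", le8_components())
  cycles <- sort(unique(data$cycle))

  est <- list()
  groups <- c(list(overall = rep("all", nrow(data))),
              setNames(lapply(config$subgroups, function(g) data[[g]]),
                       config$subgroups))
  for (gname in names(groups)) {
    gvals <- groups[[gname]]
    for (glev in sort(unique(gvals[!is.na(gvals)]))) {
      for (cy in cycles) {
        dom <- !is.na(gvals) & gvals == glev & data$cycle == cy
        for (m in metrics) {
          crude <- svy_mean(design, m, domain = dom)
          std <- tryCatch(
            svy_mean_std(design, m, std_pop = config$std_pop, domain = dom),
            error = function(e) NULL)
          est[[length(est) + 1]] <- data.frame(
            subgroup = gname, level = glev, cycle = cy, metric = m,
            n = crude$n,
            crude = crude$estimate, crude_se = crude$se,
            crude_lo = crude$ci[1], crude_hi = crude$ci[2],
            std = if (is.null(std)) NA_real_ else std$estimate,
            std_se = if (is.null(std)) NA_real_ else std$se,
            std_lo = if (is.null(std)) NA_real_ else std$ci[1],
            std_hi = if (is.null(std)) NA_real_ else std$ci[2],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  estimates <- do.call(rbind, est)
  rownames(estimates) <- NULL
  log1(stage = "estimate", rows = nrow(estimates))

  categories <- category_distributions(data, design, config$std_pop, tables,
                                       log1)

  trends <- list()
  for (m in metrics) {
    tr <- trend_regression(data, m, covariates = config$covariates,
                           design = design, cycle_levels = cycles)
    trends[[length(trends) + 1]] <- data.frame(
      metric = m, slope = tr$slope, se = tr$se, p_value = tr$p_value,
      df = tr$df, n = tr$n, stringsAsFactors = FALSE)
  }
  trends <- do.call(rbind, trends)
  log1(stage = "trend", metrics = nrow(trends))

  homog <- list()
  for (g in config$subgroups) {
    h <- tryCatch(category_homogeneity_test(data[[g]], data$cycle, design),
                  error = function(e) NULL)
    if (!is.null(h))
      homog[[length(homog) + 1]] <- data.frame(
        characteristic = g, statistic = h$statistic, df = h$df,
        p_value = h$p_value, deff = h$deff, stringsAsFactors = FALSE)
  }
  homogeneity <- if (length(homog)) do.call(rbind, homog) else NULL

  report <- list(flow = excl$flow, estimates = estimates,
                 categories = categories, trends = trends,
                 homogeneity = homogeneity,
                 provenance = list(
                   config_hash = config_hash(config),
                   seed = config$simulation$seed,
                   diet_min_recalls = config$diet_min_recalls,
                   package_version =
                     as.character(utils::packageVersion("le8trends"))),
                 logs = logs)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) emit_tables(report, config$out_dir)
  report
}

# Age-standardized category-distribution table: standardize each category's
# indicator mean per band, then renormalize to sum to 1 across categories.
category_distributions <- function(data, design, std_pop, tables, log1) {
  metrics <- c("cvh", le8_components())
  cycles <- sort(unique(data$cycle))
  labs <- tables$categories$labels
  out <- list()
  for (m in metrics) {
    cat_m <- categorize(pmin(data[[m]], 100), tables)
    for (cy in cycles) {
      dom <- data$cycle == cy
      props <- vapply(labs, function(lb) {
        e <- tryCatch(svy_mean_std(design, as.numeric(cat_m == lb),
                                   std_pop = std_pop, domain = dom),
                      error = function(e) NULL)
        if (is.null(e)) NA_real_ else e$estimate
      }, numeric(1))
      tot <- sum(props)
      if (is.finite(tot) && tot > 0 && abs(tot - 1) > 1e-12) {
        log1(stage = "categories", metric = m, cycle = cy,
             renormalization_delta = tot - 1)
        props <- props / tot
      }
      out[[length(out) + 1]] <- data.frame(
        metric = m, cycle = cy, category = labs, proportion = unname(props),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE, digits = NA)
  # small stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.run_report <- function(x, ...) {
  print(x$flow)
  cat(sprintf("Estimates: %d rows over %d metrics; trends:\n",
              nrow(x$estimates), nrow(x$trends)))
  print(x$trends, digits = 3)
  invisible(x)
}

#' Write the report tables to disk
#'
#' One CSV and one JSON file per table (estimates per stratifier, category
#' distributions, trends, homogeneity tests, exclusion flow, provenance);
#' parsed JSON and CSV agree value-for-value.
#'
#' @param report a \code{run_report}.
#' @param out_dir output directory (created if absent).
#' @param format \code{"both"} (default), \code{"csv"} or \code{"json"}.
#' @return invisibly, the paths written.
#' @export
emit_tables <- function(report, out_dir, format = c("both", "csv", "json")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("emit_tables: cannot create output directory: ", out_dir)
  paths <- character()
  put <- function(obj, name) {
    if (format %in% c("both", "csv") && is.data.frame(obj)) {
      p <- file.path(out_dir, paste0(name, ".csv"))
      write.csv(obj, p, row.names = FALSE, na = "")
      paths <<- c(paths, p)
    }
    if (format %in% c("both", "json")) {
      p <- file.path(out_dir, paste0(name, ".json"))
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "rows")
      paths <<- c(paths, p)
    }
  }
  for (g in unique(report$estimates$subgroup))
    put(report$estimates[report$estimates$subgroup == g, ],
        paste0("estimates_", g))
  put(report$categories, "category_distributions")
  put(report$trends, "trends")
  if (!is.null(report$homogeneity)) put(report$homogeneity, "homogeneity")
  put(list(initial = report$flow$initial, stages = report$flow$stages,
           final = report$flow$final), "exclusion_flow")
  put(report$provenance, "provenance")
  invisible(paths)
}
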