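# Healthy Eating Index-2015: densities and piecewise-linear component scores.

#' HEI-2015 scoring standards
#'
#' Returns the scoring-standards table for the 13 HEI-2015 components. Each
#' component is scored piecewise-linearly from its dietary density (amount per
#' 1,000 kcal, percent of energy, or a fatty-acid ratio). Adequacy components
#' reach full points at \code{max_std} and zero at \code{min_std}; moderation
#' components reach full points at or below \code{min_std} and zero at or
#' above \code{max_std}.
#'
#' The defaults are the published HEI-2015 standards. The table is ordinary
#' data and can be edited (or loaded from JSON with
#' \code{\link{read_hei_standards}}) to express other HEI vintages.
#'
#' @return A data.frame with columns \code{component}, \code{direction}
#'   (\code{"adequacy"} or \code{"moderation"}), \code{max_points},
#'   \code{min_std}, \code{max_std}, \code{density} (how the density is
#'   built: \code{"per1000"}, \code{"pct_energy"} or \code{"fa_ratio"}), and
#'   attributes \code{kcal_per_tsp_sugar} (16) and \code{kcal_per_g_fat} (9).
#' @export
#' @examples
#' hei_standards()
hei_standards <- function() {
  std <- data.frame(
    component = c("total_fruits", "whole_fruits", "total_veg", "greens_beans",
                  "whole_grains", "dairy", "total_protein",
                  "seafood_plant_protein", "fatty_acids",
                  "refined_grains", "sodium", "added_sugars", "sat_fat"),
    direction = c(rep("adequacy", 9), rep("moderation", 4)),
    max_points = c(5, 5, 5, 5, 10, 10, 5, 5, 10, 10, 10, 10, 10),
    min_std = c(0, 0, 0, 0, 0, 0, 0, 0, 1.2,
                1.8, 1.1, 6.5, 8),
    max_std = c(0.8, 0.4, 1.1, 0.2, 1.5, 1.3, 2.5, 0.8, 2.5,
                4.3, 2.0, 26, 16),
    density = c(rep("per1000", 8), "fa_ratio",
                "per1000", "per1000", "pct_energy", "pct_energy"),
    stringsAsFactors = FALSE
  )
  attr(std, "kcal_per_tsp_sugar") <- 16
  attr(std, "kcal_per_g_fat") <- 9
  std
}

#' Read or write an HEI standards table as JSON
#'
#' @param path file path.
#' @param standards a standards data.frame as returned by
#'   \code{\link{hei_standards}}.
#' @return \code{read_hei_standards}: the standards data.frame.
#' @export
read_hei_standards <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- as.data.frame(obj$components, stringsAsFactors = FALSE)
  attr(std, "kcal_per_tsp_sugar") <- obj$kcal_per_tsp_sugar
  attr(std, "kcal_per_g_fat") <- obj$kcal_per_g_fat
  validate_hei_standards(std)
  std
}

#' @rdname read_hei_standards
#' @export
write_hei_standards <- function(standards, path) {
  validate_hei_standards(standards)
  jsonlite::write_json(
    list(kcal_per_tsp_sugar = attr(standards, "kcal_per_tsp_sugar"),
         kcal_per_g_fat = attr(standards, "kcal_per_g_fat"),
         components = standards),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

validate_hei_standards <- function(std) {
  need <- c("component", "direction", "max_points", "min_std", "max_std",
            "density")
  if (!all(need %in% names(std)))
    stop("HEI standards table lacks columns: ",
         paste(setdiff(need, names(std)), collapse = ", "))
  bad <- std$min_std >= std$max_std
  if (any(bad))
    stop("HEI standards: min_std must be < max_std for component(s): ",
         paste(std$component[bad], collapse = ", "))
  invisible(std)
}

#' Names of the per-recall intake fields
#'
#' The intake columns expected for each 24-hour recall (prefixed
#' \code{r1_}/\code{r2_} in the canonical cohort dictionary).
#'
#' @return character vector of field names.
#' @export
recall_fields <- function() {
  c("energy_kcal", "total_fruits", "whole_fruits", "total_veg",
    "greens_beans", "dairy", "whole_grains", "refined_grains",
    "total_protein", "seafood_plant_protein", "sodium_g",
    "added_sugars_tsp", "satfat_g", "mufa_g", "pufa_g")
}

# Which intake field feeds each HEI component.
hei_component_field <- function() {
  c(total_fruits = "total_fruits", whole_fruits = "whole_fruits",
    total_veg = "total_veg", greens_beans = "greens_beans",
    whole_grains = "whole_grains", dairy = "dairy",
    total_protein = "total_protein",
    seafood_plant_protein = "seafood_plant_protein",
    fatty_acids = NA_character_,  # built from mufa/pufa/satfat
    refined_grains = "refined_grains", sodium = "sodium_g",
    added_sugars = "added_sugars_tsp", sat_fat = "satfat_g")
}

#' Dietary density for one HEI-2015 component
#'
#' Converts raw daily amounts into the density the HEI-2015 standards are
#' expressed in: amount per 1,000 kcal for cup/oz/gram components, percent of
#' energy for added sugars (16 kcal per teaspoon) and saturated fat (9 kcal
#' per gram), and the (MUFA + PUFA) / SFA ratio for the fatty-acid component.
#'
#' @param recall a data.frame of recall intakes (columns named as in
#'   \code{\link{recall_fields}}); one row per recall. Vectorized.
#' @param component one of the 13 component names in
#'   \code{hei_standards()$component}.
#' @param standards standards table (for the energy-conversion constants).
#' @return numeric vector of densities. A zero saturated-fat denominator
#'   yields \code{Inf} (scored as full points downstream).
#' @export
#' @examples
#' r <- data.frame(energy_kcal = 2000, total_fruits = 0.8, whole_fruits = 0.4,
#'                 total_veg = 1, greens_beans = 0, dairy = 1, whole_grains = 1,
#'                 refined_grains = 3, total_protein = 5,
#'                 seafood_plant_protein = 1, sodium_g = 3, added_sugars_tsp = 10,
#'                 satfat_g = 20, mufa_g = 30, pufa_g = 15)
#' component_density(r, "total_fruits")  # 0.4 cup per 1,000 kcal
component_density <- function(recall, component, standards = hei_standards()) {
  energy <- recall$energy_kcal
  if (any(!is.na(energy) & energy <= 0))
    stop("component_density: energy_kcal must be > 0 to form densities")
  std <- standards[match(component, standards$component), ]
  if (is.na(std$component))
    stop("unknown HEI component: ", component)
  kcal_tsp <- attr(standards, "kcal_per_tsp_sugar") %||% 16
  kcal_fat <- attr(standards, "kcal_per_g_fat") %||% 9
  switch(std$density,
    per1000 = {
      amt <- recall[[hei_component_field()[[component]]]]
      amt * 1000 / energy
    },
    pct_energy = {
      amt <- recall[[hei_component_field()[[component]]]]
      kcal <- if (component == "added_sugars") amt * kcal_tsp else amt * kcal_fat
      kcal * 100 / energy
    },
    fa_ratio = {
      num <- recall$mufa_g + recall$pufa_g
      den <- recall$satfat_g
      # zero saturated fat: limit ratio is infinite (full points) when any
      # unsaturated fat is present, zero when there is no fat at all
      ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
    },
    stop("unknown density type: ", std$density))
}

#' Piecewise-linear HEI component score
#'
#' Adequacy: 0 points at \code{min_std} (usually 0 density), full points at or
#' above \code{max_std}, linear in between. Moderation: full points at or
#' below \code{min_std}, 0 points at or above \code{max_std}, linear in
#' between. The result is clamped to \code{[0, max_points]}.
#'
#' @param density numeric vector of densities (may contain \code{Inf} for the
#'   fatty-acid ratio with zero saturated fat, and \code{NA}).
#' @param min_std,max_std,max_points,direction scalar standards for one
#'   component.
#' @return numeric vector of points.
#' @export
score_component <- function(density, min_std, max_std, max_points,
                            direction = c("adequacy", "moderation")) {
  direction <- match.arg(direction)
  if (min_std >= max_std)
    stop("score_component: min_std must be < max_std")
  frac <- (density - min_std) / (max_std - min_std)
  frac[is.infinite(density) & density > 0] <- 1
  if (direction == "moderation") frac <- 1 - frac
  pmin(pmax(frac, 0), 1) * max_points
}

#' Score one or more 24-hour recalls with HEI-2015
#'
#' @param recall data.frame of recall intakes (one row per recall, columns as
#'   in \code{\link{recall_fields}}).
#' @param standards standards table.
#' @return data.frame with one column per component score plus \code{total}
#'   (0-100). Rows with missing energy or any missing intake get \code{NA}
#'   totals.
#' @export
score_recall <- function(recall, standards = hei_standards()) {
  out <- data.frame(row.names = seq_len(nrow(recall)))
  for (k in seq_len(nrow(standards))) {
    std <- standards[k, ]
    dens <- component_density(recall, std$component, standards)
    out[[std$component]] <- score_component(dens, std$min_std, std$max_std,
                                            std$max_points, std$direction)
  }
  out$total <- rowSums(out)
  out
}

#' Person-level HEI-2015 from up to two recalls
#'
#' Averages per-recall HEI totals over the available (non-missing) recalls.
#' A person with fewer than \code{min_recalls} scoreable recalls gets
#' \code{NA}; this implements the primary analysis (two recalls required) and
#' the one-recall sensitivity analysis. With \code{method = "pooled"} the
#' intakes of the available recalls are averaged first and the mean intake is
#' scored once.
#'
#' @param recall1,recall2 data.frames of recall intakes (same rows = persons);
#'   a recall is considered missing for a person when its energy is \code{NA}.
#' @param min_recalls minimum number of recalls required (1 or 2).
#' @param method \code{"mean_of_totals"} (default) or \code{"pooled"}.
#' @param standards standards table.
#' @return numeric vector of person-level HEI totals (\code{NA} when the
#'   recall requirement is not met).
#' @export
person_hei <- function(recall1, recall2, min_recalls = 2,
                       method = c("mean_of_totals", "pooled"),
                       standards = hei_standards()) {
  method <- match.arg(method)
  stopifnot(min_recalls %in% c(1, 2))
  ok1 <- recall_complete(recall1)
  ok2 <- recall_complete(recall2)
  n_ok <- ok1 + ok2
  if (method == "mean_of_totals") {
    t1 <- t2 <- rep(NA_real_, nrow(recall1))
    if (any(ok1)) t1[ok1] <- score_recall(recall1[ok1, , drop = FALSE],
                                          standards)$total
    if (any(ok2)) t2[ok2] <- score_recall(recall2[ok2, , drop = FALSE],
                                          standards)$total
    tot <- rowMeans(cbind(t1, t2), na.rm = TRUE)
  } else {
    pooled <- recall1
    for (f in recall_fields()) {
      a <- ifelse(ok1, recall1[[f]], NA_real_)
      b <- ifelse(ok2, recall2[[f]], NA_real_)
      pooled[[f]] <- rowMeans(cbind(a, b), na.rm = TRUE)
    }
    tot <- rep(NA_real_, nrow(recall1))
    any_ok <- n_ok >= 1
    if (any(any_ok)) tot[any_ok] <- score_recall(pooled[any_ok, , drop = FALSE],
                                                 standards)$total
  }
  tot[n_ok < min_recalls] <- NA_real_
  tot
}

# A recall row is usable when energy and all intake fields are present.
recall_complete <- function(recall) {
  ok <- !is.na(recall$energy_kcal) & recall$energy_kcal > 0
  for (f in setdiff(recall_fields(), "energy_kcal")) ok <- ok & !is.na(recall[[f]])
  ok
}

`%||%` <- function(a, b) if (is.null(a)) b else a
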