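# Independent oracle implementations and record builders shared by the
# tests. The oracles are deliberately written as scalar, loop-based code on
# a different path from the package's vectorized implementations.

# ---- record builder ---------------------------------------------------------

# One complete canonical cohort row with healthy defaults; override any field.
make_person <- function(..., id = "p1") {
  rec <- list(
    id = id, cycle = "2005-2006", stratum = "s1", psu = "1", weight = 1,
    age = 45, sex = "female", race_ethnicity = "NH-White",
    education = "CollegeGrad", marital = "married",
    income_poverty_ratio = 3.5, pregnant = FALSE, breastfeeding = FALSE,
    cvd_history = FALSE,
    moderate_pa_min_wk = 200, vigorous_pa_min_wk = 0,
    smoking_status = "never", other_nicotine_use = FALSE,
    household_shs = FALSE, sleep_hours = 8,
    height_cm = 170, weight_kg = 65,
    sbp_1 = 112, sbp_2 = 110, sbp_3 = 112,
    dbp_1 = 72, dbp_2 = 70, dbp_3 = 72,
    bp_med = FALSE, non_hdl_mgdl = 110, lipid_med = FALSE,
    fasting_glucose_mgdl = 90, hba1c_pct = 5.2,
    diabetes_history = FALSE, glucose_med = FALSE)
  for (k in 1:2) {
    rec[paste0("r", k, "_", recall_fields())] <- list(
      2000, 1.8, 0.9, 2.4, 0.5, 2.7, 3.2, 3.4, 5.2, 1.7, 2.1, 6.0, 16, 40, 25)
  }
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_cohort <- function(n, ...) {
  rows <- lapply(seq_len(n), function(i) make_person(id = paste0("p", i)))
  do.call(rbind, rows)
}

# ---- Taylor-linearization oracle -------------------------------------------

# Loop-based replicate of the linearized ratio-mean SE: per-PSU totals of
# w*(y - ybar)/W computed with explicit loops, stratum by stratum.
oracle_taylor_se <- function(values, weights, strata, psu,
                             domain = rep(TRUE, length(values))) {
  W <- 0; num <- 0
  for (i in seq_along(values)) {
    if (domain[i]) {
      W <- W + weights[i]
      num <- num + weights[i] * values[i]
    }
  }
  ybar <- num / W
  key <- paste(strata, psu, sep = "|")
  v <- 0
  for (s in unique(strata)) {
    psus <- unique(key[strata == s])
    nh <- length(psus)
    zt <- numeric(nh)
    for (j in seq_along(psus)) {
      idx <- which(key == psus[j] & domain)
      for (i in idx) zt[j] <- zt[j] + weights[i] * (values[i] - ybar) / W
    }
    if (nh > 1) v <- v + nh / (nh - 1) * sum((zt - mean(zt))^2)
    else stop("oracle: singleton PSU")
  }
  list(mean = ybar, se = sqrt(v))
}

# Random small survey designs for the oracle-equivalence checks.
random_design <- function(n_strata = 3, psus = 2, n_per_psu = 10) {
  n <- n_strata * psus * n_per_psu
  data.frame(
    y = rnorm(n, 50, 10),
    w = exp(rnorm(n, 0, 0.5)),
    stratum = rep(seq_len(n_strata), each = psus * n_per_psu),
    psu = rep(rep(seq_len(psus), each = n_per_psu), n_strata))
}

# ---- HEI-2015 per-record oracle --------------------------------------------

# Scalar recomputation of the 13 component scores for one recall row.
oracle_hei_total <- function(r) {
  lin_adeq <- function(dens, std, pts) {
    if (is.na(dens)) return(NA_real_)
    if (dens >= std) pts else if (dens <= 0) 0 else dens / std * pts
  }
  lin_mod <- function(dens, lo, hi, pts) {
    if (is.na(dens)) return(NA_real_)
    if (dens <= lo) pts else if (dens >= hi) 0 else
      (hi - dens) / (hi - lo) * pts
  }
  e <- r$energy_kcal
  per1000 <- function(x) x * 1000 / e
  total <- lin_adeq(per1000(r$total_fruits), 0.8, 5) +
    lin_adeq(per1000(r$whole_fruits), 0.4, 5) +
    lin_adeq(per1000(r$total_veg), 1.1, 5) +
    lin_adeq(per1000(r$greens_beans), 0.2, 5) +
    lin_adeq(per1000(r$whole_grains), 1.5, 10) +
    lin_adeq(per1000(r$dairy), 1.3, 10) +
    lin_adeq(per1000(r$total_protein), 2.5, 5) +
    lin_adeq(per1000(r$seafood_plant_protein), 0.8, 5)
  ratio <- if (r$satfat_g > 0) (r$mufa_g + r$pufa_g) / r$satfat_g else
    if (r$mufa_g + r$pufa_g > 0) Inf else 0
  fa <- if (ratio >= 2.5) 10 else if (ratio <= 1.2) 0 else
    (ratio - 1.2) / (2.5 - 1.2) * 10
  total <- total + fa +
    lin_mod(per1000(r$refined_grains), 1.8, 4.3, 10) +
    lin_mod(per1000(r$sodium_g), 1.1, 2.0, 10) +
    lin_mod(r$added_sugars_tsp * 16 * 100 / e, 6.5, 26, 10) +
    lin_mod(r$satfat_g * 9 * 100 / e, 8, 16, 10)
  total
}

# ---- LE8 per-record oracle --------------------------------------------------

# Scalar if/else recomputation of the eight component scores for one cohort
# row (diet from a precomputed HEI and fixed cutoffs).
oracle_le8_record <- function(p, hei, cutoffs) {
  diet <- if (is.na(hei)) NA_real_ else if (hei >= cutoffs[4]) 100 else
    if (hei >= cutoffs[3]) 80 else if (hei >= cutoffs[2]) 50 else
      if (hei >= cutoffs[1]) 25 else 0

  tot <- p$moderate_pa_min_wk + 2 * p$vigorous_pa_min_wk
  pa <- if (is.na(tot)) NA_real_ else if (tot >= 150) 100 else
    if (tot >= 120) 90 else if (tot >= 90) 80 else if (tot >= 60) 60 else
      if (tot >= 30) 40 else if (tot > 0) 20 else 0

  nic <- if (is.na(p$smoking_status) || is.na(p$other_nicotine_use))
    NA_real_
  else if (p$other_nicotine_use) 0
  else switch(p$smoking_status, never = 100, former_quit_ge5y = 75,
              former_quit_1to5y = 50, former_quit_lt1y = 25, current = 0)
  if (!is.na(nic) && nic > 0) {
    if (is.na(p$household_shs)) nic <- NA_real_
    else if (p$household_shs) nic <- max(nic - 20, 0)
  }

  s <- p$sleep_hours
  slp <- if (is.na(s)) NA_real_ else if (s >= 10) 40 else if (s >= 9) 90 else
    if (s >= 7) 100 else if (s >= 6) 70 else if (s >= 5) 40 else
      if (s >= 4) 20 else 0

  b <- p$weight_kg / (p$height_cm / 100)^2
  bmi <- if (is.na(b)) NA_real_ else if (b < 25) 100 else if (b < 30) 70 else
    if (b < 35) 30 else if (b < 40) 15 else 0

  l <- p$non_hdl_mgdl
  lip <- if (is.na(l) || is.na(p$lipid_med)) NA_real_ else {
    base <- if (l < 130) 100 else if (l < 160) 60 else if (l < 190) 40 else
      if (l < 220) 20 else 0
    if (p$lipid_med && base > 0) max(base - 20, 0) else base
  }

  glu <- local({
    fbg <- p$fasting_glucose_mgdl; a1c <- p$hba1c_pct
    if (is.na(p$diabetes_history) || is.na(p$glucose_med)) return(NA_real_)
    diab <- p$diabetes_history || p$glucose_med ||
      (!is.na(fbg) && fbg >= 126) || (!is.na(a1c) && a1c >= 6.5)
    if (diab) {
      if (is.na(a1c)) NA_real_ else if (a1c < 7) 40 else if (a1c < 8) 30 else
        if (a1c < 9) 20 else if (a1c < 10) 10 else 0
    } else if (!is.na(fbg)) {
      if (fbg < 100) 100 else 60
    } else if (!is.na(a1c)) {
      if (a1c < 5.7) 100 else 60
    } else NA_real_
  })

  sbps <- c(p$sbp_1, p$sbp_2, p$sbp_3); dbps <- c(p$dbp_1, p$dbp_2, p$dbp_3)
  nr <- sum(!is.na(sbps))
  sbp <- if (nr >= 3) mean(sbps[2:3]) else if (nr == 2) mean(sbps[1:2]) else
    if (nr == 1) sbps[1] else NA_real_
  dbp <- if (nr >= 3) mean(dbps[2:3]) else if (nr == 2) mean(dbps[1:2]) else
    if (nr == 1) dbps[1] else NA_real_
  bp <- if (is.na(sbp) || is.na(p$bp_med)) NA_real_ else {
    base <- if (sbp >= 160 || dbp >= 100) 0 else
      if (sbp >= 140 || dbp >= 90) 25 else
        if (sbp >= 130 || dbp >= 80) 50 else if (sbp >= 120) 75 else 100
    if (p$bp_med && base > 0) max(base - 20, 0) else base
  }

  c(diet = diet, pa = pa, nicotine = nic, sleep = slp, bmi = bmi,
    lipids = lip, glucose = glu, bp = bp)
}

# Random complete cohort rows spanning all ladder cells, for the
# vectorized-vs-oracle equivalence checks.
random_scorable_cohort <- function(n) {
  d <- make_cohort(1)[rep(1, n), ]
  d$id <- paste0("p", seq_len(n))
  d$moderate_pa_min_wk <- sample(c(0, 10, 45, 75, 100, 130, 300), n, TRUE)
  d$vigorous_pa_min_wk <- sample(c(0, 10, 40, 100), n, TRUE)
  d$smoking_status <- sample(names(scoring_tables()$nicotine_base), n, TRUE)
  d$other_nicotine_use <- runif(n) < 0.1
  d$household_shs <- runif(n) < 0.3
  d$sleep_hours <- round(runif(n, 2, 13), 1)
  d$height_cm <- round(runif(n, 150, 195), 1)
  d$weight_kg <- round(runif(n, 45, 160), 1)
  d$non_hdl_mgdl <- round(runif(n, 60, 280))
  d$lipid_med <- runif(n) < 0.3
  d$bp_med <- runif(n) < 0.3
  sbp <- round(runif(n, 95, 185))
  dbp <- round(pmin(runif(n, 55, 115), sbp - 10))
  for (k in 1:3) {
    d[[paste0("sbp_", k)]] <- sbp + sample(-3:3, n, TRUE)
    d[[paste0("dbp_", k)]] <- pmin(dbp + sample(-3:3, n, TRUE),
                                   d[[paste0("sbp_", k)]] - 5)
  }
  d$diabetes_history <- runif(n) < 0.15
  d$glucose_med <- runif(n) < 0.1
  d$fasting_glucose_mgdl <- round(runif(n, 70, 220))
  d$hba1c_pct <- round(runif(n, 4.5, 11), 1)
  for (k in 1:2) {
    d[[paste0("r", k, "_energy_kcal")]] <- round(runif(n, 900, 3800))
    for (f in setdiff(recall_fields(), "energy_kcal"))
      d[[paste0("r", k, "_", f)]] <- round(runif(n, 0, 6), 3)
  }
  rownames(d) <- NULL
  d
}
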