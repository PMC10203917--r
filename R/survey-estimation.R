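# Design-based estimation for stratified multistage samples: weighted means
# with Taylor-linearized (between-PSU within-stratum) variances, domain
# estimation, weighted percentiles, direct age standardization, weighted
# trend regression with a stratum/PSU cluster-robust sandwich, and a
# Rao-Scott corrected chi-square homogeneity test.

#' Declare a survey design
#'
#' @param data data.frame holding the design columns.
#' @param strata,psu,weight column names (PSU ids are nested in strata; they
#'   need not be unique across strata).
#' @param lonely_psu policy for strata with a single sampled PSU:
#'   \code{"fail"} (default), \code{"collapse"} (merge the stratum with the
#'   next one), or \code{"center"} (deviation from the grand PSU-total mean,
#'   as a conservative variance contribution).
#' @return an object of class \code{svy_design}.
#' @export
svy_design <- function(data, strata = "stratum", psu = "psu",
                       weight = "weight",
                       lonely_psu = c("fail", "collapse", "center")) {
  lonely_psu <- match.arg(lonely_psu)
  miss <- setdiff(c(strata, psu, weight), names(data))
  if (length(miss))
    stop("svy_design: missing design columns: ", paste(miss, collapse = ", "))
  w <- data[[weight]]
  if (any(is.na(w)) || any(w <= 0))
    stop("svy_design: weights must be positive and non-missing")
  out <- list(data = data,
              strata = as.character(data[[strata]]),
              psu = paste(data[[strata]], data[[psu]], sep = "//"),
              weight = w,
              lonely_psu = lonely_psu)
  class(out) <- "svy_design"
  out
}

#' @export
print.svy_design <- function(x, ...) {
  cat(sprintf("Survey design: %d observations, %d strata, %d PSUs (df = %d)\n",
              length(x$weight), length(unique(x$strata)),
              length(unique(x$psu)), svy_df(x)))
  invisible(x)
}

#' Design degrees of freedom (PSUs minus strata)
#' @param design a \code{svy_design}.
#' @export
svy_df <- function(design) {
  length(unique(design$psu)) - length(unique(design$strata))
}

#' Weighted mean
#'
#' @param values numeric vector, no missing values.
#' @param weights positive weights, same length.
#' @return \eqn{\sum w x / \sum w}.
#' @export
weighted_mean <- function(values, weights) {
  if (!length(values)) stop("weighted_mean: empty input")
  if (length(values) != length(weights))
    stop("weighted_mean: lengths differ")
  if (any(is.na(values)) || any(is.na(weights)))
    stop("weighted_mean: missing values not allowed")
  if (any(weights <= 0)) stop("weighted_mean: weights must be > 0")
  sum(weights * values) / sum(weights)
}

# Between-PSU within-stratum variance of a set of per-observation linearized
# contributions z (already scaled so that var(sum z) is wanted). Returns the
# variance estimate, applying the lonely-PSU policy.
psu_variance <- function(z, strata, psu, lonely_psu = "fail") {
  zt <- rowsum(z, psu, reorder = FALSE)
  st <- strata[!duplicated(psu)]
  if (lonely_psu == "collapse") {
    nh <- table(st)
    singles <- names(nh)[nh == 1]
    if (length(singles)) {
      lev <- unique(st)
      for (s in singles) {
        i <- match(s, lev)
        partner <- if (i < length(lev)) lev[i + 1] else lev[i - 1]
        st[st == s] <- partner
      }
    }
  }
  v <- 0
  grand_mean <- colMeans(as.matrix(zt))
  for (s in unique(st)) {
    rows <- which(st == s)
    nh <- length(rows)
    zh <- as.matrix(zt)[rows, , drop = FALSE]
    if (nh == 1) {
      if (lonely_psu == "center") {
        dev <- sweep(zh, 2, grand_mean)
        v <- v + crossprod(dev)
      } else {
        stop("singleton PSU in stratum '", s,
             "'; set lonely_psu to 'collapse' or 'center' to proceed")
      }
    } else {
      dev <- sweep(zh, 2, colMeans(zh))
      v <- v + nh / (nh - 1) * crossprod(dev)
    }
  }
  v
}

#' Taylor-linearized standard error of a weighted mean
#'
#' Linearizes the ratio estimator \eqn{\bar y = \sum wy / \sum w}: each
#' observation contributes \eqn{z_i = w_i (y_i - \bar y) / \sum_D w}, the
#' contributions are totaled per PSU, and the between-PSU variance within
#' each stratum (with the finite factor \eqn{n_h/(n_h-1)}) is summed over
#' strata. For domain (subgroup) estimation, observations outside the domain
#' contribute zero but the full PSU structure is retained.
#'
#' @param values,weights numeric vectors over the full sample (values may be
#'   NA outside the domain).
#' @param strata,psu design identifiers over the full sample.
#' @param domain logical mask of domain membership (default all).
#' @param lonely_psu see \code{\link{svy_design}}.
#' @return list with \code{mean}, \code{se}, \code{df} (PSUs minus strata,
#'   over strata present in the sample), \code{n} (domain size).
#' @export
taylor_se_mean <- function(values, weights, strata, psu,
                           domain = rep(TRUE, length(values)),
                           lonely_psu = "fail") {
  stopifnot(length(values) == length(weights),
            length(values) == length(strata),
            length(values) == length(psu))
  psu <- paste(strata, psu, sep = "//")
  domain <- domain & !is.na(domain)
  if (!any(domain)) stop("taylor_se_mean: empty domain")
  if (any(is.na(values[domain])))
    stop("taylor_se_mean: missing values inside the domain")
  wd <- sum(weights[domain])
  est <- sum(weights[domain] * values[domain]) / wd
  z <- numeric(length(values))
  z[domain] <- weights[domain] * (values[domain] - est) / wd
  v <- psu_variance(z, strata, psu, lonely_psu)
  df <- length(unique(psu)) - length(unique(strata))
  list(mean = est, se = sqrt(as.numeric(v)), df = df, n = sum(domain))
}

#' Design-based mean with confidence interval
#'
#' @param design a \code{\link{svy_design}}.
#' @param x column name or numeric vector to average.
#' @param domain optional logical mask (subgroup estimation).
#' @param level confidence level.
#' @return a \code{svy_estimate}: list with \code{estimate}, \code{se},
#'   \code{ci} (t-based with design df), \code{df}, \code{n}.
#' @export
svy_mean <- function(design, x, domain = NULL, level = 0.95) {
  vals <- if (is.character(x)) design$data[[x]] else x
  if (is.null(domain)) domain <- rep(TRUE, length(vals))
  domain <- domain & !is.na(vals)
  r <- taylor_se_mean(vals, design$weight, design$strata, design$psu,
                      domain = domain, lonely_psu = design$lonely_psu)
  svy_estimate(r$mean, r$se, r$df, r$n, level)
}

svy_estimate <- function(estimate, se, df, n, level = 0.95) {
  tq <- if (df > 0) qt(1 - (1 - level) / 2, df) else NA_real_
  out <- list(estimate = estimate, se = se,
              ci = c(lower = estimate - tq * se, upper = estimate + tq * se),
              df = df, n = n, level = level)
  class(out) <- "svy_estimate"
  out
}

#' @export
print.svy_estimate <- function(x, ...) {
  cat(sprintf("%.3f (SE %.4f, %g%% CI %.3f-%.3f, df %d, n %d)\n",
              x$estimate, x$se, 100 * x$level, x$ci[1], x$ci[2], x$df, x$n))
  invisible(x)
}

#' Weighted percentiles
#'
#' The p-th percentile is the smallest observed value whose cumulative
#' normalized weight reaches p; ties are deterministic (tied values pool
#' their weight).
#'
#' @param values,weights numeric vectors (no missing values, weights > 0).
#' @param p probabilities in [0, 1].
#' @return numeric vector of cutoffs, one per element of \code{p}.
#' @export
weighted_percentile <- function(values, weights, p) {
  if (!length(values)) stop("weighted_percentile: empty input")
  if (any(is.na(values)) || any(is.na(weights)))
    stop("weighted_percentile: missing values not allowed")
  if (any(weights <= 0)) stop("weighted_percentile: weights must be > 0")
  stopifnot(all(p >= 0), all(p <= 1))
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  # guard against floating-point undershoot at p = 1
  cw[length(cw)] <- 1
  vapply(p, function(pp) v[which(cw >= pp - 1e-12)[1]], numeric(1))
}

#' Standard population for direct age standardization
#'
#' The 2018 US adult age distribution used as the standard: 20-39 years
#' 38.6%, 40-64 years 44.6%, 65-79 years 16.8%.
#'
#' @return named numeric vector of band weights summing to 1.
#' @export
std_pop_us2018 <- function() {
  w <- c("20-39" = 0.386, "40-64" = 0.446, "65-79" = 0.168)
  w / sum(w)
}

#' Age bands of a standard population
#'
#' @param age numeric ages.
#' @param std_pop named band weights (names "lo-hi").
#' @return character vector of band labels (NA outside all bands).
#' @export
age_band <- function(age, std_pop = std_pop_us2018()) {
  lims <- do.call(rbind, lapply(strsplit(names(std_pop), "-"), as.numeric))
  out <- rep(NA_character_, length(age))
  for (k in seq_len(nrow(lims)))
    out[!is.na(age) & age >= lims[k, 1] & age <= lims[k, 2]] <-
      names(std_pop)[k]
  out
}

#' Direct age standardization of band estimates
#'
#' Combines per-age-band estimates with fixed standard-population weights:
#' the standardized estimate is \eqn{\sum_b W_b \hat\theta_b} and its
#' variance \eqn{\sum_b W_b^2 \,\mathrm{se}_b^2} (bands treated as
#' independent); the df is the minimum band df.
#'
#' @param band_estimates named list of \code{svy_estimate}s (or lists with
#'   \code{estimate}, \code{se}, \code{df}, \code{n}), one per band of
#'   \code{std_pop}.
#' @param std_pop named band weights (renormalized to sum to 1).
#' @param level confidence level.
#' @return a \code{svy_estimate}.
#' @export
age_standardize <- function(band_estimates, std_pop = std_pop_us2018(),
                            level = 0.95) {
  miss <- setdiff(names(std_pop), names(band_estimates))
  if (length(miss))
    stop("age_standardize: missing band estimate(s): ",
         paste(miss, collapse = ", "))
  W <- std_pop / sum(std_pop)
  est <- sum(vapply(names(W), function(b) W[[b]] *
                      band_estimates[[b]]$estimate, numeric(1)))
  v <- sum(vapply(names(W), function(b) W[[b]]^2 *
                    band_estimates[[b]]$se^2, numeric(1)))
  df <- min(vapply(names(W), function(b) band_estimates[[b]]$df, numeric(1)))
  n <- sum(vapply(names(W), function(b) band_estimates[[b]]$n, numeric(1)))
  svy_estimate(est, sqrt(v), df, n, level)
}

#' Age-standardized design-based mean
#'
#' Convenience wrapper: estimates the mean of \code{x} within each age band
#' of \code{std_pop} (as survey domains) and directly standardizes.
#'
#' @inheritParams svy_mean
#' @param age column name or vector of ages.
#' @param std_pop standard population (named band weights).
#' @export
svy_mean_std <- function(design, x, age = "age", std_pop = std_pop_us2018(),
                         domain = NULL, level = 0.95) {
  ages <- if (is.character(age)) design$data[[age]] else age
  band <- age_band(ages, std_pop)
  if (is.null(domain)) domain <- rep(TRUE, length(ages))
  ests <- lapply(names(std_pop), function(b)
    svy_mean(design, x, domain = domain & !is.na(band) & band == b, level))
  names(ests) <- names(std_pop)
  age_standardize(ests, std_pop, level)
}

#' Survey-weighted linear regression with cluster-robust variance
#'
#' Weighted least squares with a Taylor-linearized (sandwich) covariance:
#' score contributions \eqn{u_i = w_i x_i e_i} are totaled per PSU and their
#' between-PSU within-stratum covariance forms the meat. Inference uses t
#' with design df (PSUs minus strata).
#'
#' @param formula model formula evaluated in \code{design$data}.
#' @param design a \code{\link{svy_design}}.
#' @return object of class \code{svy_lm}: coefficients, se, t, p, vcov, df.
#' @export
svy_lm <- function(formula, design) {
  mf <- stats::model.frame(formula, design$data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  keep <- complete.cases(cbind(y, X))
  if (!all(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
  }
  w <- design$weight[keep]
  strata <- design$strata[keep]
  psu <- design$psu[keep]
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("svy_lm: collinear terms: ", paste(aliased, collapse = ", "))
  }
  fit <- lm.wfit(X, y, w)
  beta <- fit$coefficients
  e <- y - drop(X %*% beta)
  A <- crossprod(X, w * X)
  U <- X * (w * e)
  G <- psu_variance(U, strata, psu, design$lonely_psu)
  Ainv <- solve(A)
  V <- Ainv %*% G %*% Ainv
  se <- sqrt(diag(V))
  df <- length(unique(psu)) - length(unique(strata))
  # a zero sandwich SE arises only from exactly fitted outcomes; a
  # numerically-zero coefficient there is a true zero (p = 1)
  tol0 <- 1e-10 * max(1, abs(y))
  tval <- ifelse(se > 0, beta / se, ifelse(abs(beta) < tol0, 0, Inf))
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  out <- list(coefficients = beta, se = se, t = tval, p = pval,
              vcov = V, df = df, n = length(y), residuals = e,
              formula = formula)
  class(out) <- "svy_lm"
  out
}

#' @export
print.svy_lm <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p)
  cat(sprintf("Survey-weighted linear model (n = %d, design df = %d)\n",
              x$n, x$df))
  print(tab, digits = 4)
  invisible(x)
}

#' Covariate-adjusted linear trend across survey cycles
#'
#' Regresses a person-level outcome on the ordered cycle index (0, 1, ...)
#' plus categorical covariate indicators, with survey weights and
#' stratum/PSU cluster-robust (linearized) variance. The p-value of the
#' cycle term is the "P for trend".
#'
#' @param data person-level data.frame containing the outcome, a
#'   \code{cycle} column (character labels or numeric), covariates and the
#'   design columns.
#' @param outcome outcome column name.
#' @param covariates character vector of covariate column names (coerced to
#'   factors).
#' @param design a \code{\link{svy_design}} built on \code{data}, or NULL to
#'   build one from the standard column names.
#' @param cycle_levels optional explicit ordering of cycle labels.
#' @return a \code{trend_result}: list with \code{slope}, \code{se},
#'   \code{p_value}, \code{df}, \code{covariates}, \code{fit}.
#' @export
trend_regression <- function(data, outcome, covariates = character(),
                             design = NULL, cycle_levels = NULL) {
  if (is.null(design)) design <- svy_design(data)
  cyc <- data$cycle
  if (is.numeric(cyc)) {
    data$cycle_index <- cyc - min(cyc, na.rm = TRUE)
  } else {
    lev <- cycle_levels %||% sort(unique(as.character(cyc)))
    data$cycle_index <- match(as.character(cyc), lev) - 1
  }
  for (cv in covariates) data[[cv]] <- factor(data[[cv]])
  design$data <- data
  rhs <- paste(c("cycle_index", covariates), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- svy_lm(f, design)
  out <- list(slope = unname(fit$coefficients["cycle_index"]),
              se = unname(fit$se["cycle_index"]),
              p_value = unname(fit$p["cycle_index"]),
              df = fit$df, n = fit$n, covariates = covariates, fit = fit)
  class(out) <- "trend_result"
  out
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Linear trend: %.4f per cycle (SE %.4f, p = %.3g, df = %d, n = %d)\n",
    x$slope, x$se, x$p_value, x$df, x$n))
  if (length(x$covariates))
    cat("Adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square homogeneity test across survey cycles
#'
#' Tests whether a categorical distribution differs across cycles. Without a
#' design this is the classical Pearson chi-square on the counts (no
#' continuity correction). With a design, the Pearson statistic is computed
#' on design-weighted proportions (scaled by the per-cycle sample sizes) and
#' divided by a first-order Rao-Scott correction — the mean generalized
#' design effect of the cell proportions — and referred to the chi-square
#' distribution with (R-1)(C-1) df.
#'
#' @param x for the classical test: a counts matrix (rows = cycles). For the
#'   design-based test: a character/factor vector of categories.
#' @param by cycle labels per observation (design-based test).
#' @param design a \code{\link{svy_design}} (or NULL for the classical test
#'   on a counts matrix).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{deff} (mean generalized design effect; 1 for the classical test).
#' @export
category_homogeneity_test <- function(x, by = NULL, design = NULL) {
  if (is.null(design)) {
    counts <- if (is.matrix(x)) x else as.matrix(table(by, x))
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    if (any(colSums(counts) == 0))
      warning("dropping zero-margin categories")
    if (nrow(counts) < 2 || ncol(counts) < 2)
      stop("need at least 2 cycles and 2 categories")
    n_r <- rowSums(counts)
    p_rc <- counts / n_r
    p_c <- colSums(counts) / sum(counts)
    stat <- sum(n_r * (p_rc - rep(p_c, each = nrow(counts)))^2 /
                  rep(p_c, each = nrow(counts)))
    df <- (nrow(counts) - 1) * (ncol(counts) - 1)
    return(list(statistic = stat, df = df,
                p_value = pchisq(stat, df, lower.tail = FALSE), deff = 1))
  }
  stopifnot(!is.null(by))
  keep <- !is.na(x) & !is.na(by)
  x <- as.character(x)[keep]; by <- as.character(by)[keep]
  cats <- sort(unique(x)); cycles <- sort(unique(by))
  zero <- vapply(cats, function(cc) sum(x == cc) == 0, logical(1))
  if (any(zero)) {
    warning("dropping zero-margin categories: ",
            paste(cats[zero], collapse = ", "))
    cats <- cats[!zero]
  }
  if (length(cycles) < 2 || length(cats) < 2)
    stop("need at least 2 cycles and 2 categories")
  w <- design$weight[keep]
  strata <- design$strata[keep]; psu <- design$psu[keep]
  R <- length(cycles); C <- length(cats)
  p_hat <- matrix(NA_real_, R, C, dimnames = list(cycles, cats))
  v_hat <- matrix(NA_real_, R, C)
  n_r <- numeric(R)
  for (r in seq_len(R)) {
    dom <- by == cycles[r]
    n_r[r] <- sum(dom)
    for (c in seq_len(C)) {
      ind <- as.numeric(x == cats[c])
      est <- taylor_se_mean(ind, w, strata, psu, domain = dom,
                            lonely_psu = design$lonely_psu)
      p_hat[r, c] <- est$mean
      v_hat[r, c] <- est$se^2
    }
  }
  p_c <- colSums(p_hat * n_r) / sum(n_r)
  stat_p <- sum(n_r * sweep(p_hat, 2, p_c)^2 /
                  rep(p_c, each = R))
  # first-order correction: mean design effect of the cell proportions
  deff_rc <- v_hat / (p_hat * (1 - p_hat) / n_r)
  deff_rc[!is.finite(deff_rc)] <- NA
  dbar <- mean(deff_rc, na.rm = TRUE)
  if (!is.finite(dbar) || dbar <= 0) dbar <- 1
  stat <- stat_p / dbar
  df <- (R - 1) * (C - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), deff = dbar)
}
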