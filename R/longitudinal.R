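ckd_epi_params <- function() {
  list(kappa_female = 0.7, kappa_male = 0.9,
       alpha_female = -0.329, alpha_male = -0.411,
       slope_exp_max = -1.209, age_base = 0.993,
       female_mult = 1.018, black_mult = 1.159)
}

#' CKD-EPI 2009 creatinine eGFR
#'
#' Estimated glomerular filtration rate in mL/min/1.73 m^2:
#' `141 x min(Scr/k, 1)^a x max(Scr/k, 1)^-1.209 x 0.993^age` with
#' `k = 0.7 / 0.9` and `a = -0.329 / -0.411` for women / men, a 1.018
#' multiplier for women and optionally 1.159 for black ethnicity (default
#' off; appropriate for Nordic cohorts).  Creatinine values above 30 are
#' assumed to be in umol/L and converted (/ 88.4) with a warning; pass
#' `unit = "umol_l"` or `"mg_dl"` to be explicit.
#'
#' @param scr Serum creatinine (> 0).
#' @param age Age in years (> 0).
#' @param sex `"female"` or `"male"` (vectorized).
#' @param black Black ethnicity multiplier flag. Default `FALSE`.
#' @param unit `"auto"` (default), `"mg_dl"` or `"umol_l"`.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
ckd_epi_egfr <- function(scr, age, sex, black = FALSE,
                         unit = c("auto", "mg_dl", "umol_l")) {
  unit <- match.arg(unit)
  if (any(scr <= 0) || any(age <= 0)) {
    abort("ckd_epi_egfr(): creatinine and age must be positive.")
  }
  if (unit == "umol_l") {
    scr <- scr / 88.4
  } else if (unit == "auto" && any(scr > 30)) {
    warn("ckd_epi_egfr(): creatinine > 30 treated as umol/L (divided by 88.4).")
    scr <- ifelse(scr > 30, scr / 88.4, scr)
  }
  p <- ckd_epi_params()
  female <- sex == "female"
  kappa <- ifelse(female, p$kappa_female, p$kappa_male)
  alpha <- ifelse(female, p$alpha_female, p$alpha_male)
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^p$slope_exp_max *
    p$age_base^age * ifelse(female, p$female_mult, 1) *
    ifelse(black, p$black_mult, 1)
}

#' Annual eGFR means per person
#'
#' Arithmetic mean of all eGFR values within each calendar year for each
#' person; years without visits are absent, never imputed.
#'
#' @param longitudinal Data frame with `person_id`, `date` (Date or
#'   parseable string) and `egfr`.
#' @return A tibble with `person_id`, `year`, `egfr_mean`, `n_visits`.
#' @export
annual_egfr_means <- function(longitudinal) {
  stopifnot(is.data.frame(longitudinal),
            all(c("person_id", "date", "egfr") %in% names(longitudinal)))
  longitudinal |>
    dplyr::mutate(year = as.integer(format(as.Date(.data$date), "%Y"))) |>
    dplyr::filter(is.finite(.data$egfr)) |>
    dplyr::group_by(.data$person_id, .data$year) |>
    dplyr::summarise(egfr_mean = mean(.data$egfr),
                     n_visits = dplyr::n(), .groups = "drop")
}

#' Per-group eGFR slopes over calendar time
#'
#' Persons with more than `min_years` annual eGFR means are retained; for
#' each group, the group-mean trajectory (mean of the annual means across
#' persons, per year) is regressed on calendar year by OLS, giving one
#' slope +/- SE per group.  Per-person OLS slopes are computed alongside for
#' downstream ROC and regression analyses.
#'
#' @param annual Data frame from [annual_egfr_means()].
#' @param groups Data frame with `person_id` and a `group` column assigning
#'   each person to a stratum (e.g. stress-score quartile).
#' @param min_years Minimum annual data points per person, strict
#'   (`> min_years`). Default 8.
#' @return A tibble of class `uev_slopes` with `group`, `slope`, `se`,
#'   `n_persons`, `n_years`; per-person slopes as attribute `"per_person"`
#'   and the per-year group mean series as attribute `"annual_means"`.
#' @export
group_slope <- function(annual, groups, min_years = 8) {
  stopifnot(all(c("person_id", "year", "egfr_mean") %in% names(annual)),
            all(c("person_id", "group") %in% names(groups)))
  counts <- annual |>
    dplyr::count(.data$person_id, name = "n_years")
  eligible <- counts$person_id[counts$n_years > min_years]
  dat <- annual |>
    dplyr::filter(.data$person_id %in% eligible) |>
    dplyr::inner_join(groups, by = "person_id")
  if (nrow(dat) == 0) {
    abort("group_slope(): no person has enough annual data points.")
  }
  per_person <- dat |>
    dplyr::group_by(.data$person_id, .data$group) |>
    dplyr::summarise(
      slope = unname(coef(lm(egfr_mean ~ year,
                             data = dplyr::pick(dplyr::everything())))[2]),
      n_years = dplyr::n(), .groups = "drop")
  annual_means <- dat |>
    dplyr::group_by(.data$group, .data$year) |>
    dplyr::summarise(egfr_mean = mean(.data$egfr_mean),
                     n_persons = dplyr::n_distinct(.data$person_id),
                     .groups = "drop")
  res <- annual_means |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        abort("group_slope(): a group has < 2 usable years.")
      }
      fit <- lm(egfr_mean ~ year, data = d)
      se <- suppressWarnings(summary(fit))$coefficients["year", "Std. Error"]
      if (!is.finite(se) || all(abs(stats::residuals(fit)) < 1e-10)) se <- 0
      tibble(slope = unname(coef(fit)[2]), se = se,
             n_persons = max(d$n_persons), n_years = nrow(d))
    }) |>
    dplyr::ungroup()
  structure(res, class = c("uev_slopes", class(res)),
            per_person = per_person, annual_means = annual_means,
            min_years = min_years)
}

#' CKD stage from annual eGFR means
#'
#' A person is staged 3-5 when at least `min_low_years` annual mean eGFR
#' values fall below `egfr_cut` (60 mL/min/1.73 m^2), given at least
#' `min_years_data` years of data; staged 1-2 otherwise; insufficient data
#' when fewer years are available.
#'
#' @param annual Data frame from [annual_egfr_means()] (one or many persons).
#' @param egfr_cut Threshold. Default 60.
#' @param min_years_data Minimum years of data to stage. Default 5.
#' @param min_low_years Annual means below the cut required for stage 3-5.
#'   Default 2.
#' @return A tibble with `person_id`, `n_years`, `n_low_years`, `stage`
#'   (`stage_1_2`, `stage_3_5` or `insufficient_data`).
#' @export
ckd_stage <- function(annual, egfr_cut = 60, min_years_data = 5,
                      min_low_years = 2) {
  stopifnot(all(c("person_id", "year", "egfr_mean") %in% names(annual)))
  annual |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      n_low_years = sum(.data$egfr_mean < egfr_cut),
      .groups = "drop") |>
    dplyr::mutate(stage = dplyr::case_when(
      n_years < min_years_data ~ "insufficient_data",
      n_low_years >= min_low_years ~ "stage_3_5",
      TRUE ~ "stage_1_2"
    ))
}

#' Adjusted regression of eGFR slope on the stress score
#'
#' Inverse-normal-transforms the per-person eGFR slope and all predictors to
#' sd units, then fits a multiple OLS of slope on stress score and clinical
#' covariates (diastolic and systolic blood pressure, HbA1c, baseline eGFR
#' by default).  Near-singular design matrices trigger a warning and a
#' small-ridge fallback flagged in the output.
#'
#' @param data Data frame containing the outcome and predictor columns.
#' @param outcome Outcome column (per-person eGFR slope).
#'   Default `"slope"`.
#' @param predictors Predictor columns.  Default
#'   `c("score", "dbp", "hba1c", "sbp", "egfr_baseline")`.
#' @param condition_limit Condition-number threshold for the collinearity
#'   guard. Default 1e8.
#' @return A tibble of class `uev_slope_reg` with `term`, `estimate`, `se`,
#'   `p_value`; attributes `n`, `r_squared`, `ridged` (logical).
#' @export
adjusted_slope_regression <- function(data, outcome = "slope",
                                      predictors = c("score", "dbp", "hba1c",
                                                     "sbp", "egfr_baseline"),
                                      condition_limit = 1e8) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(predictors %in% names(data)))
  cols <- c(outcome, predictors)
  dat <- data[stats::complete.cases(data[cols]), cols]
  n <- nrow(dat)
  if (n <= length(predictors) + 2) {
    abort("adjusted_slope_regression(): n must exceed predictors + 2.")
  }
  z <- as.data.frame(lapply(dat, inverse_normal_transform))
  x <- as.matrix(cbind(`(Intercept)` = 1, z[predictors]))
  y <- z[[outcome]]
  kap <- kappa(crossprod(x), exact = TRUE)
  ridged <- FALSE
  if (!is.finite(kap) || kap > condition_limit) {
    warn("adjusted_slope_regression(): near-collinear predictors; ridge fallback.")
    ridged <- TRUE
    lambda <- 1e-6 * n
    xtx <- crossprod(x) + diag(lambda, ncol(x))
    beta <- solve(xtx, crossprod(x, y))
    resid <- y - x %*% beta
    s2 <- sum(resid^2) / (n - ncol(x))
    covb <- s2 * solve(xtx) %*% crossprod(x) %*% solve(xtx)
    se <- sqrt(diag(covb))
    tval <- beta / se
    pv <- 2 * stats::pt(-abs(tval), df = n - ncol(x))
    est <- as.numeric(beta)
    r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  } else {
    fit <- lm(y ~ . - 1, data = as.data.frame(x))
    sm <- summary(fit)
    est <- unname(coef(fit))
    se <- sm$coefficients[, "Std. Error"]
    pv <- sm$coefficients[, "Pr(>|t|)"]
    r2 <- sm$r.squared
  }
  out <- tibble(term = c("(Intercept)", predictors),
                estimate = est, se = unname(se), p_value = unname(pv))
  structure(out, class = c("uev_slope_reg", class(out)),
            n = n, r_squared = r2, ridged = ridged)
}

#' Albuminuria classification
#'
#' Classifies persons into normo-, micro- and macroalbuminuria under the
#' study-specific rule sets:
#' * `finndiane_24h` - AER in mg/24 h; macro > 300, micro 30-300 (closed
#'   interval), normo < 30; the category must be met in `repeats_required`
#'   (default 2) of the last 3 consecutive collections.
#' * `direva_on` - at the last visit, macro when AER (ug/min) > 200 or ACR
#'   (mg/mmol) > 35; micro when AER 20-200 or ACR > 3.5; normo requires
#'   AER < 20 and ACR < 3.5 at all visits.
#' * `ibeat_kdigo` - ACR (mg/mmol), sex-specific: macro > 25 (men) / 35
#'   (women), micro 2.5-25 / 3.5-35, normo below.
#'
#' Boundary values on "< x" style bounds go to the lower category; the
#' 30-300 micro interval is closed.
#'
#' @param measurements Data frame with `person_id` and, depending on the
#'   rule, `aer` and/or `acr`, plus a visit order column `visit` (integer;
#'   last = largest).
#' @param cohort_rule `"finndiane_24h"`, `"direva_on"` or `"ibeat_kdigo"`.
#' @param sex Data frame `person_id`, `sex` (needed for `ibeat_kdigo`).
#' @param repeats_required Collections (of the last 3) that must meet the
#'   category under `finndiane_24h`. Default 2.
#' @return A tibble with `person_id`, `albuminuria`
#'   (factor normo/micro/macro).
#' @export
classify_albuminuria <- function(measurements,
                                 cohort_rule = c("finndiane_24h", "direva_on",
                                                 "ibeat_kdigo"),
                                 sex = NULL, repeats_required = 2) {
  cohort_rule <- match.arg(cohort_rule)
  stopifnot(is.data.frame(measurements), "person_id" %in% names(measurements))
  m <- as_tibble(measurements)
  if (!"visit" %in% names(m)) m$visit <- 1L

  lev <- c("normo", "micro", "macro")
  cat_factor <- function(x) factor(x, levels = lev)

  if (cohort_rule == "finndiane_24h") {
    if (!"aer" %in% names(m)) abort("classify_albuminuria(): finndiane_24h needs aer (mg/24h).")
    res <- m |>
      dplyr::group_by(.data$person_id) |>
      dplyr::arrange(.data$visit, .by_group = TRUE) |>
      dplyr::summarise(albuminuria = {
        a <- utils::tail(.data$aer, 3)
        cats <- ifelse(a > 300, "macro", ifelse(a >= 30, "micro", "normo"))
        if (sum(cats %in% c("macro")) >= repeats_required) "macro"
        else if (sum(cats %in% c("macro", "micro")) >= repeats_required) "micro"
        else "normo"
      }, .groups = "drop")
  } else if (cohort_rule == "direva_on") {
    if (!any(c("aer", "acr") %in% names(m))) {
      abort("classify_albuminuria(): direva_on needs aer (ug/min) and/or acr (mg/mmol).")
    }
    if (!"aer" %in% names(m)) m$aer <- NA_real_
    if (!"acr" %in% names(m)) m$acr <- NA_real_
    res <- m |>
      dplyr::group_by(.data$person_id) |>
      dplyr::arrange(.data$visit, .by_group = TRUE) |>
      dplyr::summarise(albuminuria = {
        last_aer <- utils::tail(.data$aer, 1)
        last_acr <- utils::tail(.data$acr, 1)
        macro <- isTRUE(last_aer > 200) || isTRUE(last_acr > 35)
        micro <- isTRUE(last_aer >= 20) || isTRUE(last_acr > 3.5)
        if (macro) "macro" else if (micro) "micro" else "normo"
      }, .groups = "drop")
  } else {
    if (!"acr" %in% names(m)) abort("classify_albuminuria(): ibeat_kdigo needs acr (mg/mmol).")
    if (is.null(sex)) abort("classify_albuminuria(): ibeat_kdigo needs sex.")
    m <- dplyr::left_join(m, sex, by = "person_id")
    if (any(is.na(m$sex))) abort("classify_albuminuria(): missing sex for some persons.")
    res <- m |>
      dplyr::group_by(.data$person_id) |>
      dplyr::arrange(.data$visit, .by_group = TRUE) |>
      dplyr::summarise(albuminuria = {
        acr <- utils::tail(.data$acr, 1)
        female <- utils::tail(.data$sex, 1) == "female"
        hi <- if (female) 35 else 25
        lo <- if (female) 3.5 else 2.5
        if (acr > hi) "macro" else if (acr >= lo) "micro" else "normo"
      }, .groups = "drop")
  }
  res$albuminuria <- cat_factor(res$albuminuria)
  res
}
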