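#' Five-component additive precariousness score
#'
#' Computes the five dichotomous precarity indicators for working nurses and
#' their unweighted sum (0--5):
#' \describe{
#'   \item{salary_flag}{1 if income is up to two times the minimum wage
#'     (`income_mw <= salary_mw_multiple`, boundary inclusive)}
#'   \item{workday_flag}{1 if weekly hours are part-time or extended time
#'     (`< 34` or `> 48`; the 34--48 h band inclusive is unflagged)}
#'   \item{contract_flag}{1 if no written contract}
#'   \item{benefits_flag}{1 if no social benefit at all}
#'   \item{social_security_flag}{1 if no self-reported access to
#'     health-institution services (social security)}
#' }
#' The score is the plain sum of the five flags; `level` dichotomizes it at
#' `high_cut` (default 3: a majority of adverse components) into
#' `non_or_low` vs `high` precariousness.
#'
#' @param records Working-nurse microdata rows (underemployed or employed in
#'   the health sector); hours and income must be present and non-negative.
#' @param high_cut Score threshold for the `high` precarity level.
#' @param salary_mw_multiple Minimum-wage multiple defining the low-salary
#'   flag (default 2).
#' @param hours_low,hours_high Workday band bounds (default 34 and 48).
#' @return A tibble with the five flag columns, `score` and `level`.
#' @export
precarity_components <- function(records, high_cut = 3L,
                                 salary_mw_multiple = 2,
                                 hours_low = 34, hours_high = 48) {
  if (any(!records$working)) {
    abort_domain("precarity components are defined only for working records")
  }
  need <- employment_fields()
  if (any(!complete.cases(records[, need, drop = FALSE]))) {
    abort_validation("missing employment fields; build the analytic sample first")
  }
  if (any(records$weekly_hours < 0) || any(records$income_mw < 0)) {
    abort_validation("weekly_hours and income_mw must be non-negative")
  }
  flags <- tibble::tibble(
    salary_flag = as.integer(records$income_mw <= salary_mw_multiple),
    workday_flag = as.integer(records$weekly_hours < hours_low |
                                records$weekly_hours > hours_high),
    contract_flag = as.integer(!records$written_contract),
    benefits_flag = as.integer(!records$any_social_benefit),
    social_security_flag = as.integer(!records$ss_health_access)
  )
  flags$score <- flags$salary_flag + flags$workday_flag + flags$contract_flag +
    flags$benefits_flag + flags$social_security_flag
  flags$level <- classify_precarity_level(flags$score, high_cut)
  flags
}

#' Precarity level from an additive score
#'
#' @param score Integer score(s) in 0--5.
#' @param high_cut Threshold: scores `>= high_cut` are `high`, below it
#'   `non_or_low`. Default 3.
#' @return Factor with levels `non_or_low`, `high`.
#' @export
classify_precarity_level <- function(score, high_cut = 3L) {
  if (any(is.na(score)) || any(score < 0 | score > 5)) {
    abort_validation("score must lie in 0-5")
  }
  if (high_cut < 1 || high_cut > 5) abort_validation("high_cut must lie in 1-5")
  factor(ifelse(score >= high_cut, "high", "non_or_low"),
         levels = c("non_or_low", "high"))
}

#' Labor-market performance outcome: non-precarious health-sector employment
#'
#' The study's headline outcome: 1 if and only if the nurse is employed in
#' the health sector with a precarity score of exactly zero. Defined on the
#' working population only (underemployed nurses always score 0 on the
#' outcome regardless of their precarity).
#'
#' @param status Labor-status factor from [classify_labor_status()].
#' @param score Precarity score 0--5.
#' @return Integer 0/1 vector.
#' @export
market_performance_outcome <- function(status, score) {
  if (any(status == "unemployed")) {
    abort_domain("outcome undefined for unemployed records")
  }
  as.integer(status == "employed_health" & score == 0L)
}

#' Attach precarity columns to an analytic sample
#'
#' Adds labor status, government period, the five precarity flags, the score,
#' the level, and the non-precarious-employment outcome to an analytic
#' sample. Unemployed records keep `NA` in the precarity and outcome columns
#' (they are retained for status distributions but excluded from the
#' regression samples).
#'
#' @inheritParams precarity_components
#' @param sample Analytic sample from [build_analytic_sample()].
#' @return The sample with columns `labor_status`, `period`, the five flags,
#'   `score`, `level` and `non_precarious_employment` appended.
#' @export
add_precarity <- function(sample, high_cut = 3L, salary_mw_multiple = 2,
                          hours_low = 34, hours_high = 48) {
  out <- sample
  out$labor_status <- classify_labor_status(out)
  out$period <- assign_period(out$year)
  flag_cols <- c("salary_flag", "workday_flag", "contract_flag",
                 "benefits_flag", "social_security_flag", "score")
  for (cl in flag_cols) out[[cl]] <- NA_integer_
  out$level <- factor(NA_character_, levels = c("non_or_low", "high"))
  out$non_precarious_employment <- NA_integer_

  w <- which(out$working)
  if (length(w) > 0) {
    comp <- precarity_components(out[w, , drop = FALSE], high_cut,
                                 salary_mw_multiple, hours_low, hours_high)
    for (cl in flag_cols) out[[cl]][w] <- comp[[cl]]
    out$level[w] <- comp$level
    out$non_precarious_employment[w] <-
      market_performance_outcome(out$labor_status[w], comp$score)
  }
  out
}

#' Convert currency income to minimum-wage multiples
#'
#' Real-data path helper: divides a currency income by the applicable
#' per-year minimum wage. The synthetic generator emits `income_mw` directly
#' and bypasses this step.
#'
#' @param income Currency income.
#' @param year Year of observation.
#' @param mw_table Tibble or data frame with columns `year` and
#'   `minimum_wage` (same currency and reference period as `income`).
#' @return Income expressed as a multiple of the minimum wage.
#' @export
income_to_mw <- function(income, year, mw_table) {
  i <- match(year, mw_table$year)
  if (any(is.na(i))) abort_config("mw_table lacks a minimum wage for some year")
  income / mw_table$minimum_wage[i]
}
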