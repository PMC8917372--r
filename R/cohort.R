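#' Labor-status classification of economically active nurses
#'
#' Classifies each economically active nurse into one of three mutually
#' exclusive, exhaustive statuses:
#' \describe{
#'   \item{unemployed}{not working for pay while available and seeking work}
#'   \item{underemployed}{working, but outside the health sector (the
#'     professional-market sense of underemployment: trained nurses absorbed
#'     by other markets)}
#'   \item{employed_health}{working in the health sector}
#' }
#'
#' @param records Microdata rows; every row must have
#'   `economically_active = TRUE` (the classifier's universe).
#' @return A factor with levels `unemployed`, `underemployed`,
#'   `employed_health`.
#' @export
classify_labor_status <- function(records) {
  if (any(!records$economically_active)) {
    abort_domain("labor status is defined only for economically active records")
  }
  out <- ifelse(!records$working, "unemployed",
                ifelse(records$in_health_sector, "employed_health", "underemployed"))
  factor(out, levels = c("unemployed", "underemployed", "employed_health"))
}

period_table <- function() {
  tibble::tibble(
    label = c("2005-2006", "2007-2009", "2010-2012",
              "2013-2015", "2016-2018", "2019"),
    from = c(2005L, 2007L, 2010L, 2013L, 2016L, 2019L),
    to   = c(2006L, 2009L, 2012L, 2015L, 2018L, 2019L)
  )
}

#' Government-period bin for a survey year
#'
#' The study window 2005--2019 is partitioned into six administration periods:
#' 2005--2006 (last two years of one administration), 2007--2009 and
#' 2010--2012, 2013--2015 and 2016--2018 (two three-year halves each), and
#' 2019 (first year of the incoming administration).
#'
#' @param year Integer vector of years in 2005--2019.
#' @return A factor of period labels with chronologically ordered levels.
#' @export
assign_period <- function(year) {
  if (any(is.na(year)) || any(year < 2005 | year > 2019)) {
    abort_domain("year must lie in 2005-2019")
  }
  pt <- period_table()
  idx <- vapply(year, function(y) which(pt$from <= y & y <= pt$to), integer(1))
  factor(pt$label[idx], levels = pt$label)
}

employment_fields <- function() {
  c("weekly_hours", "income_mw", "written_contract",
    "any_social_benefit", "ss_health_access")
}

#' Default completeness fields for the analytic sample
#' @return Character vector of schema columns required to be non-missing.
#' @export
default_required_fields <- function() {
  c(employment_fields(),
    "sex", "age_band", "marital", "university", "n_jobs", "residence", "region")
}

#' Build the analytic sample of first-visit economically active nurses
#'
#' Applies the study's sample-construction rules in order: keep first-visit
#' records only (`visit_number == 1`, removing the quarterly redundancy of
#' the rotating panel), keep nurse occupation codes, keep the economically
#' active, and drop records with missing values among `required_fields`.
#' Employment fields are checked only for working records: records of
#' unemployed nurses carry structural (not-applicable) blanks on hours,
#' income, contract, benefits and social-security access and are not
#' excluded for them.
#'
#' @param records Microdata tibble in the package schema.
#' @param nurse_codes Character set of nurse occupation codes.
#' @param required_fields Columns that must be non-missing; defaults to
#'   [default_required_fields()].
#' @return A list with `sample` (the analytic tibble, input order preserved)
#'   and `audit` (a `sample_audit` with counts for every stage).
#' @export
build_analytic_sample <- function(records,
                                  nurse_codes = nurse_codes_synthetic(),
                                  required_fields = default_required_fields()) {
  if (length(nurse_codes) == 0) abort_config("nurse_codes must not be empty")
  unknown <- setdiff(required_fields, names(records))
  if (length(unknown) > 0) {
    abort_config(paste("unknown required field(s):", paste(unknown, collapse = ", ")))
  }

  n_raw <- nrow(records)
  s1 <- records[records$visit_number == 1L, , drop = FALSE]
  n_first_visit <- nrow(s1)
  s2 <- s1[s1$occupation_code %in% nurse_codes & s1$economically_active, , drop = FALSE]
  n_nurses <- nrow(s2)

  emp_req <- intersect(required_fields, employment_fields())
  oth_req <- setdiff(required_fields, employment_fields())
  ok <- rep(TRUE, nrow(s2))
  if (length(oth_req) > 0) {
    ok <- ok & complete.cases(s2[, oth_req, drop = FALSE])
  }
  if (length(emp_req) > 0) {
    emp_ok <- complete.cases(s2[, emp_req, drop = FALSE])
    ok <- ok & (!s2$working | emp_ok)
  }
  s3 <- s2[ok, , drop = FALSE]

  audit <- structure(
    list(n_raw = n_raw, n_first_visit = n_first_visit, n_nurses = n_nurses,
         n_complete = nrow(s3), n_excluded_incomplete = n_nurses - nrow(s3)),
    class = "sample_audit"
  )
  list(sample = s3, audit = audit)
}

#' @export
print.sample_audit <- function(x, ...) {
  cat("Analytic-sample audit\n")
  cat(sprintf("  raw records            %8d\n", x$n_raw))
  cat(sprintf("  first-visit records    %8d\n", x$n_first_visit))
  cat(sprintf("  econ-active nurses     %8d\n", x$n_nurses))
  cat(sprintf("  complete (analytic)    %8d\n", x$n_complete))
  cat(sprintf("  excluded incomplete    %8d\n", x$n_excluded_incomplete))
  invisible(x)
}

#' @export
format.sample_audit <- function(x, ...) {
  paste0(names(unclass(x)), ",", unlist(unclass(x)), collapse = "\n")
}
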