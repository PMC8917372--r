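# Delimited-text microdata I/O against the package schema.

microdata_col_types <- function() {
  readr::cols(
    household_id = readr::col_integer(),
    person_id = readr::col_integer(),
    year = readr::col_integer(),
    quarter = readr::col_integer(),
    visit_number = readr::col_integer(),
    stratum_id = readr::col_integer(),
    psu_id = readr::col_integer(),
    weight = readr::col_double(),
    occupation_code = readr::col_character(),
    economically_active = readr::col_logical(),
    working = readr::col_logical(),
    available_and_seeking = readr::col_logical(),
    sector = readr::col_character(),
    in_health_sector = readr::col_logical(),
    weekly_hours = readr::col_double(),
    income_mw = readr::col_double(),
    written_contract = readr::col_logical(),
    any_social_benefit = readr::col_logical(),
    ss_health_access = readr::col_logical(),
    sex = readr::col_character(),
    age_band = readr::col_character(),
    marital = readr::col_character(),
    university = readr::col_logical(),
    n_jobs = readr::col_character(),
    residence = readr::col_character(),
    region = readr::col_integer()
  )
}

#' Write person-quarter microdata as CSV
#'
#' @param records Microdata tibble in the package schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read person-quarter microdata from CSV
#'
#' Reads a delimited microdata file and validates it against the package
#' schema (column presence and types; see
#' `system.file("extdata", "schema.csv", package = "nursemkt")`).
#'
#' @param path CSV file path.
#' @return A microdata tibble.
#' @export
read_microdata <- function(path) {
  ct <- microdata_col_types()
  out <- readr::read_csv(path, col_types = ct, na = c("", "NA"))
  missing_cols <- setdiff(names(ct$cols), names(out))
  if (length(missing_cols) > 0) {
    abort_validation(paste("microdata file lacks schema columns:",
                           paste(missing_cols, collapse = ", ")))
  }
  out
}
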