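#' Specification of one of the six nested regression models
#'
#' The analysis fits three nested models on each of two estimation samples:
#' \describe{
#'   \item{sample}{`underemployed_plus_employed` (all working nurses) or
#'     `employed_only` (health-sector employees)}
#'   \item{level 1}{survey quarter, survey year, labor sector, and the
#'     sector-by-year interaction}
#'   \item{level 2}{adds the individual sociodemographic and labor
#'     covariates: sex, age band, marital status, university education,
#'     number of jobs}
#'   \item{level 3}{adds the contextual features: place of residence and
#'     socioeconomic region}
#' }
#' Year and quarter enter as categorical factors. Under treatment coding
#' with the first survey year as reference, the `sectorpublic` coefficient
#' is the public-vs-private log odds ratio at the reference year.
#'
#' @param sample `"underemployed_plus_employed"` or `"employed_only"`.
#' @param level Integer 1, 2 or 3.
#' @param references Named list of reference categories
#'   (sector/sex/age_band/marital/n_jobs/residence/region).
#' @return A `model_spec` object with the model formula and metadata.
#' @export
build_model_spec <- function(sample = c("underemployed_plus_employed", "employed_only"),
                             level = 1L,
                             references = list(sector = "private", sex = "male",
                                               age_band = "25-54",
                                               marital = "married_union",
                                               n_jobs = "1",
                                               residence = "metropolitan",
                                               region = "1")) {
  sample <- match.arg(sample)
  if (!level %in% 1:3) abort_config("level must be 1, 2 or 3")
  base_terms <- c("quarter_f", "year_f", "sector_f", "sector_f:year_f")
  indiv <- c("sex_f", "age_band_f", "marital_f", "university", "n_jobs_f")
  context <- c("residence_f", "region_f")
  terms <- switch(level, base_terms, c(base_terms, indiv),
                  c(base_terms, indiv, context))
  formula <- as.formula(paste("non_precarious_employment ~",
                              paste(terms, collapse = " + ")))
  structure(list(sample = sample, level = as.integer(level), terms = terms,
                 formula = formula, references = references),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec: sample = %s, level = %d\n", x$sample, x$level))
  cat("  ", deparse(x$formula), "\n")
  invisible(x)
}

#' Prepare an analytic sample for model fitting
#'
#' Selects the estimation sample (working nurses, optionally health-sector
#' employees only) and builds the factor columns the model formula uses,
#' with the spec's reference categories first so treatment coding yields the
#' intended contrasts (private sector, male, age 25--54 as references, and
#' the first survey year as the sector-effect reference year).
#'
#' @param data Analytic sample with precarity columns ([add_precarity()]).
#' @param spec A [build_model_spec()] object.
#' @return The estimation-sample tibble with `*_f` factor columns appended.
#' @export
prepare_model_data <- function(data, spec) {
  d <- data[estimation_sample_rows(data, spec), , drop = FALSE]
  add_model_factors(d, spec$references)
}

estimation_sample_rows <- function(data, spec) {
  if (spec$sample == "employed_only") {
    data$labor_status == "employed_health"
  } else {
    data$labor_status != "unemployed"
  }
}

add_model_factors <- function(d, refs) {
  relevel_first <- function(x, ref) {
    x <- as.character(x)
    factor(x, levels = c(ref, setdiff(sort(unique(x), method = "radix"), ref)))
  }
  d$quarter_f <- factor(d$quarter)
  d$year_f <- factor(d$year)
  d$sector_f <- relevel_first(d$sector, refs$sector)
  d$sex_f <- relevel_first(d$sex, refs$sex)
  d$age_band_f <- relevel_first(d$age_band, refs$age_band)
  d$marital_f <- relevel_first(d$marital, refs$marital)
  d$n_jobs_f <- relevel_first(d$n_jobs, refs$n_jobs)
  d$residence_f <- relevel_first(d$residence, refs$residence)
  d$region_f <- relevel_first(as.character(d$region), refs$region)
  d
}

#' Fit one spec of the six-model grid on a full-design analytic sample
#'
#' Subsets the design to the spec's estimation sample (keeping the parent
#' PSU frame for correct subpopulation variances), builds the factor
#' contrasts, and fits the survey-weighted logistic model.
#'
#' @param design A [svy_design()] over the scored analytic sample
#'   (see [add_precarity()]).
#' @param spec A [build_model_spec()] object.
#' @param ... Passed to [fit_survey_logit()].
#' @return A `svy_logit_fit`.
#' @export
fit_model_spec <- function(design, spec, ...) {
  stopifnot(inherits(spec, "model_spec"))
  keep <- estimation_sample_rows(design$variables, spec)
  sub <- subset_svy_design(design, keep)
  sub$variables <- add_model_factors(sub$variables, spec$references)
  fit_survey_logit(spec$formula, sub, ...)
}
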