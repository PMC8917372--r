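#' Quarter grid for a study window
#'
#' Expands calendar years into an ordered (year, quarter) grid, the unit at
#' which a quarterly labor-force survey fields its rotating panel.
#'
#' @param years Integer vector of years (2005--2019 for the study window).
#' @param quarters Integer subset of 1:4.
#' @return A tibble with columns `year` and `quarter`, ordered chronologically.
#' @export
quarter_grid <- function(years = 2005:2019, quarters = 1:4) {
  stopifnot(all(quarters %in% 1:4))
  tidyr::expand_grid(year = as.integer(sort(years)), quarter = as.integer(quarters))
}

#' Default covariate distributions for the synthetic nurse population
#'
#' Marginal categorical distributions emulating the covariate mix of the
#' Mexican nursing workforce: predominantly female, working-age, metropolitan,
#' with a public-sector majority among health-sector employees.
#'
#' @return A named list of named probability vectors.
#' @export
default_covariate_dists <- function() {
  list(
    sex       = c(female = 0.90, male = 0.10),
    age_band  = c("<=24" = 0.15, "25-54" = 0.75, ">=55" = 0.10),
    marital   = c(married_union = 0.55, single = 0.35, div_widowed = 0.10),
    university = c(yes = 0.45, no = 0.55),
    sector    = c(public = 0.70, private = 0.30),
    n_jobs    = c("1" = 0.95, ">=2" = 0.05),
    residence = c(rural = 0.07, semi_urban = 0.08, urban = 0.15, metropolitan = 0.70),
    region    = c("1" = 0.13, "2" = 0.15, "3" = 0.12, "4" = 0.17, "5" = 0.20, "6" = 0.23)
  )
}

#' Default data-generating coefficients for the five precarity components
#'
#' Each component's probability of being *absent* (non-precarious on that
#' dimension) follows an independent logistic model
#' `logit P(flag = 0) = intercept + public * I(sector == public) + year * (year - 2005)`.
#' Positive `public` terms encode the protective effect of public-sector
#' employment; negative `year` terms encode the secular deterioration of
#' employment conditions over the study window. Extra named terms are matched
#' to logical record columns (e.g. `university`).
#'
#' @return A named list with one coefficient vector per component
#'   (`salary`, `workday`, `contract`, `benefits`, `social_security`).
#' @export
default_dgp_coefs <- function() {
  list(
    salary          = c(intercept = 1.2, public = 1.6, year = -0.030),
    workday         = c(intercept = 1.0, public = 1.0, year = -0.020),
    contract        = c(intercept = 2.2, public = 2.4, year = -0.035),
    benefits        = c(intercept = 1.8, public = 2.0, year = -0.030),
    social_security = c(intercept = 1.6, public = 2.0, year = -0.030)
  )
}

#' Default labor-status probabilities by year
#'
#' Linear interpolation between the observed 2005--2006 shares (5.0%
#' unemployed, 26.7% underemployed, 68.3% employed in the health sector) and
#' the 2019 shares (5.0% / 33.7% / 61.3%): stable unemployment with rising
#' professional underemployment.
#'
#' @param years Years to cover.
#' @return A tibble with columns `year`, `p_unemployed`, `p_underemployed`,
#'   `p_employed` (rows sum to 1).
#' @export
default_labor_status_probs <- function(years = 2005:2019) {
  years <- as.integer(sort(years))
  f <- if (length(years) > 1) (years - years[1]) / (max(years) - years[1]) else 0
  p_un <- rep(0.050, length(years))
  p_ue <- 0.267 + f * (0.337 - 0.267)
  tibble::tibble(
    year = years,
    p_unemployed = p_un,
    p_underemployed = p_ue,
    p_employed = 1 - p_un - p_ue
  )
}

#' Simulation parameters for the synthetic rotating-panel survey
#'
#' Bundles and validates everything [simulate_enoe()] needs: the quarter grid,
#' the household volume, the covariate mix, the stratified cluster design, and
#' the known component-level data-generating coefficients that make parameter
#' recovery testable downstream.
#'
#' @param n_households_per_quarter Households interviewed each quarter.
#' @param quarters Tibble from [quarter_grid()].
#' @param nurse_fraction Probability a household's respondent is a nursing
#'   professional (occupation in the nurse code set).
#' @param covariate_dists Named list of categorical distributions, see
#'   [default_covariate_dists()].
#' @param design List with `n_strata`, `psus_per_stratum`, `mean_weight`
#'   (expansion-factor mean, persons represented per record) and `sdlog_weight`
#'   (log-normal spread of weights).
#' @param dgp_coefs Named list of per-component coefficient vectors, see
#'   [default_dgp_coefs()].
#' @param labor_status_probs Either a length-3 probability vector
#'   (unemployed, underemployed, employed) applied to every year, or a tibble
#'   as returned by [default_labor_status_probs()].
#' @param sector_underemployed Sector mix for nurses working outside the
#'   health sector (mostly private).
#' @param econ_active_prob Probability a respondent is economically active.
#' @param missing_rate Probability a working nurse record has one employment
#'   field blanked (item nonresponse).
#' @param visits `"panel"` emits the full five-visit rotating panel;
#'   `"first_only"` emits only the rotation-in fifth of each quarter
#'   (sufficient for first-visit analyses, five times cheaper).
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @return A validated object of class `sim_params`.
#' @export
sim_params <- function(n_households_per_quarter = 20000L,
                       quarters = quarter_grid(),
                       nurse_fraction = 0.02,
                       covariate_dists = default_covariate_dists(),
                       design = list(n_strata = 32L, psus_per_stratum = 6L,
                                     mean_weight = 250, sdlog_weight = 0.5),
                       dgp_coefs = default_dgp_coefs(),
                       labor_status_probs = NULL,
                       sector_underemployed = c(public = 0.10, private = 0.90),
                       econ_active_prob = 0.95,
                       missing_rate = 0.02,
                       visits = c("panel", "first_only"),
                       seed = 20051L) {
  visits <- match.arg(visits)
  quarters <- tibble::as_tibble(quarters)
  if (nrow(quarters) == 0) abort_config("quarters list is empty")
  if (!all(c("year", "quarter") %in% names(quarters))) {
    abort_config("quarters must have columns year and quarter")
  }
  ord <- order(quarters$year, quarters$quarter)
  if (any(ord != seq_len(nrow(quarters))) || anyDuplicated(quarters) > 0) {
    abort_config("quarters must be strictly increasing")
  }
  if (n_households_per_quarter < 5) abort_config("need at least 5 households per quarter")
  if (nurse_fraction <= 0 || nurse_fraction > 1) abort_config("nurse_fraction must be in (0, 1]")
  if (missing_rate < 0 || missing_rate > 1) abort_config("missing_rate must be in [0, 1]")
  if (econ_active_prob < 0 || econ_active_prob > 1) abort_config("econ_active_prob must be in [0, 1]")
  for (nm in names(covariate_dists)) check_dist(covariate_dists[[nm]], nm)
  check_dist(sector_underemployed, "sector_underemployed")
  stopifnot(design$n_strata >= 1, design$psus_per_stratum >= 2)
  if (design$mean_weight <= 0) abort_config("mean_weight must be positive")

  comp_names <- c("salary", "workday", "contract", "benefits", "social_security")
  if (!setequal(names(dgp_coefs), comp_names)) {
    abort_config("dgp_coefs must name exactly the five components: salary, workday, contract, benefits, social_security")
  }
  for (nm in comp_names) {
    cf <- dgp_coefs[[nm]]
    if (!all(c("intercept", "public", "year") %in% names(cf))) {
      abort_config(sprintf("dgp_coefs$%s must contain intercept, public and year terms", nm))
    }
  }

  if (is.null(labor_status_probs)) {
    labor_status_probs <- default_labor_status_probs(unique(quarters$year))
  } else if (is.numeric(labor_status_probs) && length(labor_status_probs) == 3) {
    check_dist(labor_status_probs, "labor_status_probs")
    labor_status_probs <- tibble::tibble(
      year = unique(quarters$year),
      p_unemployed = labor_status_probs[1],
      p_underemployed = labor_status_probs[2],
      p_employed = labor_status_probs[3]
    )
  } else {
    labor_status_probs <- tibble::as_tibble(labor_status_probs)
  }
  apply(labor_status_probs[, c("p_unemployed", "p_underemployed", "p_employed")], 1,
        check_dist, what = "labor_status_probs")
  if (!all(unique(quarters$year) %in% labor_status_probs$year)) {
    abort_config("labor_status_probs must cover every year in quarters")
  }

  structure(
    list(
      n_households_per_quarter = as.integer(n_households_per_quarter),
      quarters = quarters,
      nurse_fraction = nurse_fraction,
      covariate_dists = covariate_dists,
      design = design,
      dgp_coefs = dgp_coefs,
      labor_status_probs = labor_status_probs,
      sector_underemployed = sector_underemployed,
      econ_active_prob = econ_active_prob,
      missing_rate = missing_rate,
      visits = visits,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic rotating-panel survey parameters\n")
  cat(sprintf("  %d households/quarter over %d quarters (%d-%d), %s visits\n",
              x$n_households_per_quarter, nrow(x$quarters),
              min(x$quarters$year), max(x$quarters$year), x$visits))
  cat(sprintf("  nurse fraction %.3f; design %d strata x %d PSUs; mean weight %.0f\n",
              x$nurse_fraction, x$design$n_strata, x$design$psus_per_stratum,
              x$design$mean_weight))
  invisible(x)
}

#' Occupation codes used by the synthetic generator
#'
#' The synthetic stand-in for an occupation-catalogue nurse code set (the real
#' survey's catalogue changed over the years and is supplied by the user for
#' real-data runs).
#'
#' @return Character vector of nurse occupation codes.
#' @export
nurse_codes_synthetic <- function() c("NUR1", "NUR2")
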