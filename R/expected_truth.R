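#' Ground-truth non-precarity probabilities implied by the generator
#'
#' Integrates the five independent component models over the covariate
#' distribution by Monte Carlo to obtain, for every (sector, year) cell, the
#' true probability that a working nurse has a precarity score of zero, and
#' the implied conditional public-vs-private odds ratio per year. Because the
#' components are generated independently given covariates, the zero-score
#' probability factorizes as the product of the five per-component
#' non-precarity probabilities; the Monte Carlo average handles any extra
#' covariate terms in `dgp_coefs`.
#'
#' Used as the oracle in parameter-recovery tests: the sector log-odds ratio
#' fitted by [fit_survey_logit()] at the reference year should recover
#' `log(sector_or$or[year == min(year)])`.
#'
#' @param params A [sim_params()] object.
#' @param n_draws Monte Carlo draws over the covariate distribution.
#' @param seed Seed for the Monte Carlo integration (independent of the
#'   microdata seed).
#' @return A list of class `enoe_truth` with elements
#'   `by_sector_year` (tibble: year, sector, p_nonprecarious),
#'   `sector_or` (tibble: year, or, log_or) and
#'   `overall` (tibble: sector, p_nonprecarious marginal over the window).
#' @export
expected_truth <- function(params, n_draws = 1e5, seed = params$seed + 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  cd <- params$covariate_dists
  profiles <- tibble::tibble(
    sex = sample_cat(n_draws, cd$sex),
    age_band = sample_cat(n_draws, cd$age_band),
    marital = sample_cat(n_draws, cd$marital),
    university = sample_cat(n_draws, cd$university) == "yes",
    n_jobs = sample_cat(n_draws, cd$n_jobs),
    residence = sample_cat(n_draws, cd$residence),
    region = as.integer(sample_cat(n_draws, cd$region))
  )
  profiles$female <- profiles$sex == "female"

  years <- sort(unique(params$quarters$year))
  year0 <- min(years)
  comp_names <- names(params$dgp_coefs)

  cells <- tidyr::expand_grid(year = years, sector = c("private", "public"))
  cells$p_nonprecarious <- vapply(seq_len(nrow(cells)), function(i) {
    recs <- profiles
    recs$sector <- cells$sector[i]
    recs$year <- cells$year[i]
    p0 <- rep(1, n_draws)
    for (nm in comp_names) {
      p0 <- p0 * plogis(component_eta(params$dgp_coefs[[nm]], recs, year0))
    }
    mean(p0)
  }, numeric(1))

  wide <- tidyr::pivot_wider(cells, names_from = "sector",
                             values_from = "p_nonprecarious")
  odds <- function(p) p / (1 - p)
  sector_or <- tibble::tibble(
    year = wide$year,
    or = odds(wide$public) / odds(wide$private)
  )
  sector_or$log_or <- log(sector_or$or)

  overall <- dplyr::summarise(dplyr::group_by(cells, .data$sector),
                              p_nonprecarious = mean(.data$p_nonprecarious),
                              .groups = "drop")

  structure(list(by_sector_year = cells, sector_or = sector_or,
                 overall = overall),
            class = "enoe_truth")
}

#' @export
print.enoe_truth <- function(x, ...) {
  cat("Generator ground truth (P[score = 0] by sector)\n")
  print(x$overall)
  cat(sprintf("Conditional public-vs-private OR at first year: %.3f\n",
              x$sector_or$or[1]))
  invisible(x)
}
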