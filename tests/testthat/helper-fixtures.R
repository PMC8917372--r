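# Shared fixture builders. Everything is generated in code at test time.

# small, fast simulation setup (first-visit records only)
tiny_params <- function(seed = 101, n_hh = 1500, years = 2005:2008, ...) {
  sim_params(n_households_per_quarter = n_hh,
             quarters = quarter_grid(years),
             nurse_fraction = 0.5, visits = "first_only", seed = seed, ...)
}

# simulation setup for parameter-recovery runs: every respondent a working
# nurse, mostly employed in the health sector
recovery_params <- function(seed, n_hh = 9800, years = 2005:2007) {
  sim_params(n_households_per_quarter = n_hh,
             quarters = quarter_grid(years),
             nurse_fraction = 1, econ_active_prob = 1, missing_rate = 0,
             labor_status_probs = c(0.03, 0.12, 0.85),
             visits = "first_only", seed = seed)
}

# independent-sampling design: one PSU per record, one stratum
srs_design <- function(data) {
  data$stratum_id <- 1L
  data$psu_id <- seq_len(nrow(data))
  data$weight <- data$weight %||% rep(1, nrow(data))
  svy_design(data)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random working-nurse records with raw employment fields drawn freely
# (not via the generator's flag-consistent path)
random_working_records <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    working = TRUE,
    weekly_hours = runif(n, 0, 80),
    income_mw = runif(n, 0, 6),
    written_contract = runif(n) < 0.5,
    any_social_benefit = runif(n) < 0.5,
    ss_health_access = runif(n) < 0.5
  )
}

# logistic data on a stratified cluster design for GOF simulations
gof_sim_design <- function(n, seed, quad = 0) {
  set.seed(seed)
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1, 0.4)
  eta <- -0.5 + 0.8 * x1 + 0.6 * x2 + quad * x1^2
  d <- tibble::tibble(
    y = stats::rbinom(n, 1, stats::plogis(eta)), x1 = x1, x2 = x2,
    stratum_id = sample.int(32, n, replace = TRUE),
    weight = stats::rlnorm(n, log(100), 0.4))
  d$psu_id <- d$stratum_id * 100L + sample.int(6, n, replace = TRUE)
  svy_design(d)
}

# scored analytic sample from a simulation
scored_sample <- function(params) {
  add_precarity(build_analytic_sample(simulate_enoe(params))$sample)
}
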