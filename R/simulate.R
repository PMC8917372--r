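#' Generate synthetic rotating-panel survey microdata
#'
#' Emulates a quarterly household labor-force survey fielded as a rotating
#' panel with five-visit cycles: each quarter one fifth of the households is
#' interviewed for the first time and one fifth rotates out. One respondent is
#' generated per household. For economically active nurses, a labor status
#' (unemployed / underemployed outside the health sector / employed in the
#' health sector) is drawn per year, and the five precarity components of
#' working nurses are drawn from independent logistic models with the known
#' coefficients in `params$dgp_coefs`; the raw employment fields (hours,
#' income in minimum-wage multiples, contract, benefits, social-security
#' access) are then generated consistently with the drawn flags, so the
#' scoring rules recover them exactly.
#'
#' @param params A [sim_params()] object.
#' @return A tibble of person-quarter records following the package schema
#'   (see `system.file("extdata", "schema.csv", package = "nursemkt")`),
#'   deterministic given `params$seed`.
#' @export
simulate_enoe <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)

  qs <- params$quarters
  n_q <- nrow(qs)
  m <- max(1L, as.integer(round(params$n_households_per_quarter / 5)))

  # rotation cohorts: cohort entering at quarter index e is seen at e..e+4
  entries <- if (params$visits == "panel") seq(-3L, n_q) else seq_len(n_q)
  n_coh <- length(entries)
  n_hh <- n_coh * m

  des <- params$design
  cd <- params$covariate_dists
  hh <- tibble::tibble(
    household_id = seq_len(n_hh),
    entry = rep(entries, each = m),
    stratum_id = sample.int(des$n_strata, n_hh, replace = TRUE),
    psu_within = sample.int(des$psus_per_stratum, n_hh, replace = TRUE),
    weight = rlnorm(n_hh,
                    meanlog = log(des$mean_weight) - des$sdlog_weight^2 / 2,
                    sdlog = des$sdlog_weight),
    occupation_code = ifelse(runif(n_hh) < params$nurse_fraction,
                             sample(nurse_codes_synthetic(), n_hh, replace = TRUE),
                             "OTH0"),
    economically_active = runif(n_hh) < params$econ_active_prob,
    sex = sample_cat(n_hh, cd$sex),
    age_band = sample_cat(n_hh, cd$age_band),
    marital = sample_cat(n_hh, cd$marital),
    university = sample_cat(n_hh, cd$university) == "yes",
    n_jobs = sample_cat(n_hh, cd$n_jobs),
    residence = sample_cat(n_hh, cd$residence),
    region = as.integer(sample_cat(n_hh, cd$region))
  )
  hh$psu_id <- hh$stratum_id * 100L + hh$psu_within
  hh$person_id <- hh$household_id * 10L + 1L

  # expand households to observed quarters
  span <- if (params$visits == "panel") 0:4 else 0L
  obs <- hh[rep(seq_len(n_hh), each = length(span)), , drop = FALSE]
  obs$offset <- rep(span, times = n_hh)
  obs$qidx <- obs$entry + obs$offset
  obs <- obs[obs$qidx >= 1L & obs$qidx <= n_q, , drop = FALSE]
  obs$visit_number <- obs$offset + 1L
  obs$year <- qs$year[obs$qidx]
  obs$quarter <- qs$quarter[obs$qidx]
  obs <- obs[order(obs$qidx, obs$household_id), , drop = FALSE]
  n <- nrow(obs)

  # employment-field scaffolding
  obs$working <- FALSE
  obs$available_and_seeking <- obs$economically_active
  obs$sector <- "none"
  obs$in_health_sector <- FALSE
  obs$weekly_hours <- NA_real_
  obs$income_mw <- NA_real_
  obs$written_contract <- NA
  obs$any_social_benefit <- NA
  obs$ss_health_access <- NA

  is_nurse <- obs$occupation_code %in% nurse_codes_synthetic()
  active_nurse <- is_nurse & obs$economically_active
  other_active <- !is_nurse & obs$economically_active

  # non-nurse respondents: simple plausible employment fields (filtered out
  # downstream by the occupation rule, but schema-valid)
  n_oth <- sum(other_active)
  if (n_oth > 0) {
    obs$working[other_active] <- TRUE
    obs$sector[other_active] <- "private"
    obs$weekly_hours[other_active] <- runif(n_oth, 34, 48)
    obs$income_mw[other_active] <- runif(n_oth, 1, 6)
    obs$written_contract[other_active] <- runif(n_oth) < 0.5
    obs$any_social_benefit[other_active] <- runif(n_oth) < 0.5
    obs$ss_health_access[other_active] <- runif(n_oth) < 0.5
  }

  # labor status of economically active nurses, drawn per year
  idx <- which(active_nurse)
  if (length(idx) > 0) {
    lsp <- params$labor_status_probs
    pr <- lsp[match(obs$year[idx], lsp$year),
              c("p_unemployed", "p_underemployed", "p_employed")]
    u <- runif(length(idx))
    status <- ifelse(u < pr$p_unemployed, "unemployed",
                     ifelse(u < pr$p_unemployed + pr$p_underemployed,
                            "underemployed", "employed"))

    emp <- idx[status == "employed"]
    und <- idx[status == "underemployed"]
    obs$working[c(emp, und)] <- TRUE
    obs$in_health_sector[emp] <- TRUE
    obs$sector[emp] <- sample_cat(length(emp), cd$sector)
    obs$sector[und] <- sample_cat(length(und), params$sector_underemployed)

    work <- c(emp, und)
    if (length(work) > 0) {
      flags <- draw_component_flags(obs[work, , drop = FALSE], params)
      obs[work, c("weekly_hours", "income_mw", "written_contract",
                  "any_social_benefit", "ss_health_access")] <-
        fields_from_flags(flags)
    }
  }

  # item nonresponse on employment fields of working nurses
  if (params$missing_rate > 0) {
    cand <- which(active_nurse & obs$working)
    hit <- cand[runif(length(cand)) < params$missing_rate]
    if (length(hit) > 0) {
      fld <- c("weekly_hours", "income_mw", "written_contract",
               "any_social_benefit", "ss_health_access")[
                 sample.int(5L, length(hit), replace = TRUE)]
      for (f in unique(fld)) obs[hit[fld == f], f] <- NA
    }
  }

  cols <- c("household_id", "person_id", "year", "quarter", "visit_number",
            "stratum_id", "psu_id", "weight", "occupation_code",
            "economically_active", "working", "available_and_seeking",
            "sector", "in_health_sector", "weekly_hours", "income_mw",
            "written_contract", "any_social_benefit", "ss_health_access",
            "sex", "age_band", "marital", "university", "n_jobs",
            "residence", "region")
  out <- tibble::as_tibble(obs[, cols])
  attr(out, "sim_seed") <- params$seed
  out
}

# linear predictor of P(flag = 0) for one component on a record block;
# extra coefficient names beyond intercept/public/year are matched to
# logical or numeric columns of the records
component_eta <- function(coefs, records, year0) {
  eta <- rep(coefs[["intercept"]], nrow(records)) +
    coefs[["public"]] * as.numeric(records$sector == "public") +
    coefs[["year"]] * (records$year - year0)
  extra <- setdiff(names(coefs), c("intercept", "public", "year"))
  for (nm in extra) {
    if (!nm %in% names(records)) {
      abort_config(sprintf("dgp coefficient '%s' has no matching record column", nm))
    }
    eta <- eta + coefs[[nm]] * as.numeric(records[[nm]])
  }
  eta
}

draw_component_flags <- function(records, params) {
  year0 <- min(params$quarters$year)
  out <- matrix(0L, nrow(records), 5,
                dimnames = list(NULL, names(default_dgp_coefs())))
  for (nm in colnames(out)) {
    p0 <- plogis(component_eta(params$dgp_coefs[[nm]], records, year0))
    out[, nm] <- rbinom(nrow(records), 1L, 1 - p0)
  }
  out
}

# raw employment fields consistent with drawn flags (scoring recovers them)
fields_from_flags <- function(flags) {
  n <- nrow(flags)
  inc <- ifelse(flags[, "salary"] == 1L,
                runif(n, 0.5, 2.0), 2 + runif(n, 0.05, 6))
  short <- runif(n) < 0.5
  hrs <- ifelse(flags[, "workday"] == 1L,
                ifelse(short, runif(n, 8, 33.5), runif(n, 48.5, 72)),
                runif(n, 34, 48))
  tibble::tibble(
    weekly_hours = hrs,
    income_mw = inc,
    written_contract = flags[, "contract"] == 0L,
    any_social_benefit = flags[, "benefits"] == 0L,
    ss_health_access = flags[, "social_security"] == 0L
  )
}
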