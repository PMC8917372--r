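# Survey-weighted logistic regression, aORs, GOF, margins.

glm_fixture <- function(n = 200, seed = 8) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.3 + 0.9 * x1 - 0.7 * x2))
  tibble::tibble(y = y, x1 = x1, x2 = x2, weight = 1)
}

test_that("model specs are nested with the stated term sets", {
  s1 <- build_model_spec("employed_only", 1)
  s2 <- build_model_spec("underemployed_plus_employed", 2)
  s3 <- build_model_spec("employed_only", 3)
  expect_setequal(s1$terms, c("quarter_f", "year_f", "sector_f", "sector_f:year_f"))
  expect_true(all(s1$terms %in% s2$terms))
  expect_true(all(build_model_spec("employed_only", 2)$terms %in% s3$terms))
  expect_true(all(c("sex_f", "age_band_f", "marital_f", "university", "n_jobs_f")
                  %in% s2$terms))
  expect_false(any(c("residence_f", "region_f") %in% s2$terms))
  expect_true(all(c("residence_f", "region_f") %in% s3$terms))
  expect_error(build_model_spec("employed_only", 4), "level")
})

test_that("equal weights and independent sampling match the glm oracle to 1e-6", {
  dat <- glm_fixture()
  fit <- fit_survey_logit(y ~ x1 + x2, srs_design(dat))
  oracle <- glm(y ~ x1 + x2, family = binomial(), data = dat)
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(unname(fit$fitted), unname(fitted(oracle)), tolerance = 1e-6)
})

test_that("unequal weights match a weighted glm oracle", {
  dat <- glm_fixture(seed = 9)
  dat$weight <- rlnorm(nrow(dat), 0, 0.6)
  fit <- fit_survey_logit(y ~ x1 + x2, srs_design(dat))
  oracle <- suppressWarnings(
    glm(y ~ x1 + x2, family = quasibinomial(), data = dat, weights = weight))
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-6)
})

test_that("degenerate outcomes, separation and collinearity raise explicit errors", {
  dat <- glm_fixture()
  dat$y <- 1
  expect_error(fit_survey_logit(y ~ x1, srs_design(dat)), "constant")
  sep <- tibble::tibble(x1 = c(-2, -1, -0.5, 0.5, 1, 2), weight = 1,
                        y = c(0, 0, 0, 1, 1, 1))
  sep <- sep[rep(1:6, 10), ]
  expect_error(fit_survey_logit(y ~ x1, srs_design(sep)), "separation")
  dup <- glm_fixture()
  dup$x3 <- dup$x1 * 2
  expect_error(fit_survey_logit(y ~ x1 + x3, srs_design(dup)), "collinear")
})

test_that("pseudo-log-likelihood is monotone over the nested model levels", {
  sc <- scored_sample(recovery_params(seed = 111, n_hh = 2500, years = 2005:2006))
  d <- svy_design(sc)
  ll <- vapply(1:3, function(lvl) {
    fit_model_spec(d, build_model_spec("employed_only", lvl))$loglik
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("aOR confidence bounds are the exponentiated t-based coefficients", {
  dat <- glm_fixture()
  fit <- fit_survey_logit(y ~ x1 + x2, srs_design(dat))
  ao <- adjusted_odds_ratios(fit, "x1")
  tcrit <- qt(0.975, fit$df)
  expect_equal(ao$aor, exp(ao$beta))
  expect_equal(ao$ci_low, exp(ao$beta - tcrit * ao$se), tolerance = 1e-12)
  expect_equal(ao$ci_high, exp(ao$beta + tcrit * ao$se), tolerance = 1e-12)
  expect_true(ao$ci_low <= ao$aor && ao$aor <= ao$ci_high)
  # closed-form check: a coefficient of log 2 with margin log 1.5 at large df
  b <- log(2); margin <- log(1.5)
  expect_equal(exp(b - margin), 4 / 3, tolerance = 1e-12)
  expect_equal(exp(b + margin), 3, tolerance = 1e-12)
  expect_error(adjusted_odds_ratios(fit, "nope"), "not in model")
})

test_that("sector aOR recovers the generator truth on one synthetic draw", {
  p <- recovery_params(seed = 2121)
  sc <- scored_sample(p)
  d <- svy_design(sc)
  fit <- fit_model_spec(d, build_model_spec("employed_only", 1))
  ao <- adjusted_odds_ratios(fit, "sector_fpublic")
  truth <- exp(expected_truth(p, n_draws = 1e5)$sector_or$log_or[1])
  expect_gt(ao$ci_high, truth * 0.8)
  expect_lt(ao$ci_low, truth * 1.2)
})

test_that("GOF rejects configuration degeneracies", {
  dat <- glm_fixture()
  fit <- fit_survey_logit(y ~ x1 + x2, srs_design(dat))
  expect_error(archer_lemeshow_gof(fit, n_groups = 1), "at least 2")
  null_fit <- fit_survey_logit(y ~ 1, srs_design(dat))
  expect_error(archer_lemeshow_gof(null_fit), "distinct fitted")
})

test_that("GOF does not reject a correctly specified model on typical draws", {
  pv <- vapply(1:20, function(i) {
    archer_lemeshow_gof(fit_survey_logit(y ~ x1 + x2,
                                         gof_sim_design(1000, 400 + i)))$p_value
  }, numeric(1))
  expect_gt(mean(pv > 0.05), 0.8)
})

test_that("intercept-only margins equal the overall weighted prevalence", {
  sc <- scored_sample(tiny_params(seed = 131, n_hh = 600, years = 2005:2006))
  work <- sc[sc$labor_status != "unemployed", ]
  d <- svy_design(work)
  fit <- fit_survey_logit(non_precarious_employment ~ 1, d)
  marg <- adjusted_prevalence(fit, by = "period")
  overall <- sum(work$weight * work$non_precarious_employment) / sum(work$weight)
  # agreement up to the Newton-Raphson score tolerance
  expect_true(all(abs(marg$estimate - overall) < 1e-8))
})

test_that("margins are invariant to weight rescaling", {
  sc <- scored_sample(tiny_params(seed = 141, n_hh = 800, years = 2005:2006))
  run <- function(mult) {
    sc$weight <- sc$weight * mult
    d <- svy_design(sc)
    fit <- fit_model_spec(d, build_model_spec("employed_only", 3))
    adjusted_prevalence(fit, by = "region")
  }
  m1 <- run(1); m2 <- run(250)
  expect_equal(m1$estimate, m2$estimate, tolerance = 1e-10)
  expect_equal(m1$se, m2$se, tolerance = 1e-8)
})

test_that("margins track the generator's sector-mixed prevalence", {
  p <- recovery_params(seed = 151, n_hh = 4000, years = 2005:2006)
  sc <- scored_sample(p)
  d <- svy_design(sc)
  fit <- fit_model_spec(d, build_model_spec("employed_only", 3))
  marg <- adjusted_prevalence(fit, by = "period")
  tr <- expected_truth(p, n_draws = 5e4)
  mix <- p$covariate_dists$sector
  # both years fall in the same period bin: truth is the sector-mixed
  # prevalence averaged over 2005-2006
  byy <- tr$by_sector_year
  truth <- mean(vapply(2005:2006, function(yr) {
    sum(byy$p_nonprecarious[byy$year == yr] * mix[byy$sector[byy$year == yr]])
  }, numeric(1)))
  expect_identical(nrow(marg), 1L)
  expect_lt(abs(marg$estimate[1] - truth), 3 * marg$se[1] + 0.01)
})
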