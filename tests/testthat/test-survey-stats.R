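# Design-based proportions, Taylor variances, distributions, relative change.

test_that("equal weights under independent sampling reduce to the sample mean", {
  d <- srs_design(tibble::tibble(y = c(1, 1, 0, 0), weight = 1))
  est <- svy_prop(d, "y")
  expect_equal(est$estimate, 0.5)
})

test_that("SRS standard error equals the classical binomial formula", {
  set.seed(99)
  y <- rbinom(400, 1, 0.3)
  d <- srs_design(tibble::tibble(y = y, weight = 1))
  est <- svy_prop(d, "y")
  p <- mean(y)
  expect_equal(est$se, sqrt(p * (1 - p) / (length(y) - 1)), tolerance = 1e-10)
})

test_that("the 2x2 PSU fixture reproduces the hand-computed Taylor variance", {
  # stratum 1: PSU A records (w=2,y=1),(w=3,y=0); PSU B (w=1,y=1),(w=4,y=1)
  # stratum 2: PSU C records (w=5,y=0),(w=2,y=1); PSU D (w=3,y=0),(w=1,y=1)
  # By hand: p = 10/21. PSU totals of z_i = w_i(y_i - p)/21 are
  # A: -8/441, B: 55/441, C: -28/441, D: -19/441; stratum sums with the
  # n_h/(n_h-1) = 2 factor give V = (3969 + 81)/441^2 = 50/2401.
  fix <- tibble::tibble(
    stratum_id = c(1, 1, 1, 1, 2, 2, 2, 2),
    psu_id = c(1, 1, 2, 2, 1, 1, 2, 2),
    weight = c(2, 3, 1, 4, 5, 2, 3, 1),
    y = c(1, 0, 1, 1, 0, 1, 0, 1)
  )
  d <- svy_design(fix)
  est <- svy_prop(d, "y")
  expect_equal(est$estimate, 10 / 21, tolerance = 1e-12)
  expect_equal(est$se^2, 50 / 2401, tolerance = 1e-10)
  expect_identical(d$df, 2L)
})

test_that("estimates and margins of error are invariant to weight rescaling", {
  sc <- scored_sample(tiny_params(seed = 19, n_hh = 400, years = 2005))
  d1 <- svy_design(sc, single_psu = "collapse")
  sc2 <- sc; sc2$weight <- sc2$weight * 17.3
  d2 <- svy_design(sc2, single_psu = "collapse")
  e1 <- svy_prop(d1, sc$labor_status == "employed_health")
  e2 <- svy_prop(d2, sc$labor_status == "employed_health")
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-12)
  expect_equal(e1$se, e2$se, tolerance = 1e-12)
  expect_equal(e2$n_weighted, e1$n_weighted * 17.3, tolerance = 1e-9)
})

test_that("degenerate estimates return one-sided intervals", {
  d <- srs_design(tibble::tibble(y = rep(0, 20), weight = 1))
  est0 <- svy_prop(d, "y")
  expect_identical(est0$ci_low, 0)
  expect_gt(est0$ci_high, 0)
  d1 <- srs_design(tibble::tibble(y = rep(1, 20), weight = 1))
  est1 <- svy_prop(d1, "y")
  expect_identical(est1$ci_high, 1)
  expect_lt(est1$ci_low, 1)
})

test_that("domain estimation keeps the full design and rejects empty domains", {
  sc <- scored_sample(tiny_params(seed = 29, n_hh = 400, years = 2005))
  d <- svy_design(sc, single_psu = "collapse")
  dom <- sc$sector == "public"
  est <- svy_prop(d, sc$score == 0, domain = dom)
  expect_identical(est$n_unweighted, sum(dom))
  expect_error(svy_prop(d, sc$score == 0, domain = rep(FALSE, nrow(sc))),
               "empty domain")
})

test_that("single-PSU strata error by default and can be collapsed", {
  dat <- tibble::tibble(stratum_id = c(1, 1, 2), psu_id = c(1, 2, 1),
                        weight = 1, y = c(0, 1, 1))
  expect_error(svy_design(dat), "single PSU")
  d <- svy_design(dat, single_psu = "collapse")
  expect_identical(d$n_strata, 1L)
  expect_s3_class(svy_prop(d, "y"), "tbl_df")
})

test_that("status shares partition each period", {
  sc <- scored_sample(tiny_params(seed = 39))
  d <- svy_design(sc)
  dist <- labor_status_distribution(d)
  sums <- tapply(dist$estimate, dist$period, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_identical(nrow(dist), length(unique(dist$period)) * 3L)
  # single period in, one period out
  one <- sc[sc$period == levels(sc$period)[1], ]
  dist1 <- labor_status_distribution(svy_design(one))
  expect_identical(length(unique(dist1$period)), 1L)
})

test_that("status shares recover the generator's status probabilities", {
  probs <- c(0.05, 0.30, 0.65)
  p <- sim_params(n_households_per_quarter = 25000, quarters = quarter_grid(2005),
                  nurse_fraction = 1, econ_active_prob = 1, missing_rate = 0,
                  labor_status_probs = probs, visits = "first_only", seed = 49)
  sc <- scored_sample(p)
  d <- svy_design(sc)
  dist <- labor_status_distribution(d)
  expect_true(all(abs(dist$estimate - probs) < 3 * dist$se))
})

test_that("confidence intervals attain near-nominal coverage", {
  # many small independent-sampling replicates of a fixed true proportion
  p_true <- 0.35
  nrep <- 1000
  n <- 120
  set.seed(2024)
  covered <- vapply(seq_len(nrep), function(i) {
    y <- rbinom(n, 1, p_true)
    est <- svy_prop(srs_design(tibble::tibble(y = y, weight = 1)), "y")
    est$ci_low <= p_true && p_true <= est$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("relative change reproduces trend arithmetic", {
  expect_equal(relative_change(26.7, 33.7), 26.2)
  expect_equal(relative_change(68.6, 61.4), -10.5)
  expect_equal(relative_change(50, 50), 0)
  expect_error(relative_change(0, 10), "positive")
})
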