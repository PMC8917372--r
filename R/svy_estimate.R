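#' Design-based weighted proportion with Taylor-linearized variance
#'
#' Estimates a population proportion as the weighted ratio
#' \eqn{\hat p = \sum_i w_i y_i / \sum_i w_i} over a domain, with the variance
#' of the ratio estimator by stratified between-PSU Taylor linearization.
#' Domain (subpopulation) analysis keeps the full design: out-of-domain
#' records contribute zeros to the linearized totals, and every PSU of the
#' design frame enters the between-PSU variance, as required for correct
#' subpopulation inference.
#'
#' The 95% CI is computed on the logit scale with a t critical value at the
#' design degrees of freedom and back-transformed (the common `svy`
#' behaviour), or as a plain Wald interval with `ci_method = "wald"`.
#' Degenerate estimates (0 or 1) return a one-sided exact-binomial-style
#' bound.
#'
#' @param design A [svy_design()].
#' @param y Logical/0-1 vector aligned with `design$variables`, or the name
#'   of such a column.
#' @param domain Optional logical vector (or column name) restricting the
#'   estimate to a subpopulation; the default uses all rows.
#' @param ci_method `"logit"` (default) or `"wald"`.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate`, `se`, `ci_low`, `ci_high`,
#'   `n_unweighted`, `n_weighted`.
#' @export
svy_prop <- function(design, y, domain = NULL, ci_method = c("logit", "wald"),
                     level = 0.95) {
  stopifnot(inherits(design, "svy_design"))
  ci_method <- match.arg(ci_method)
  dat <- design$variables
  if (is.character(y) && length(y) == 1) y <- dat[[y]]
  y <- as.numeric(y)
  if (is.null(domain)) domain <- rep(TRUE, nrow(dat))
  if (is.character(domain) && length(domain) == 1) domain <- as.logical(dat[[domain]])
  if (!any(domain)) abort_domain("empty domain")
  if (any(is.na(y[domain]))) abort_validation("indicator has missing values on the domain")

  w <- dat[[design$weight_col]]
  d <- as.numeric(domain)
  W <- sum(w * d)
  p <- sum(w * d * y, na.rm = TRUE) / W

  yy <- ifelse(domain, y, 0)
  z <- (w * d * (yy - p)) / W
  V <- taylor_linearized_vcov(matrix(z, ncol = 1), design_psu_keys(design), design$psu_frame)
  se <- sqrt(V[1, 1])

  n_dom <- sum(domain)
  alpha <- 1 - level
  tcrit <- qt(1 - alpha / 2, df = max(design$df, 1))
  if (p <= 0 || p >= 1) {
    # one-sided exact-style bound for degenerate estimates
    if (p <= 0) {
      ci <- c(0, 1 - (alpha / 2)^(1 / n_dom))
    } else {
      ci <- c((alpha / 2)^(1 / n_dom), 1)
    }
  } else if (ci_method == "logit") {
    l <- qlogis(p)
    se_l <- se / (p * (1 - p))
    ci <- plogis(l + c(-1, 1) * tcrit * se_l)
  } else {
    ci <- pmin(1, pmax(0, p + c(-1, 1) * tcrit * se))
  }

  tibble::tibble(estimate = p, se = se, ci_low = ci[1], ci_high = ci[2],
                 n_unweighted = n_dom, n_weighted = W)
}

#' Labor-status distribution by period
#'
#' Per government period, the design-based shares of the three labor
#' statuses (the machine-readable twin of a status-distribution series).
#' Shares within a period sum to one.
#'
#' @param design A [svy_design()] whose variables carry `labor_status` and
#'   `period` columns (see [add_precarity()]).
#' @param by Grouping column, default `"period"`.
#' @return A tibble with one row per (group, status) and the [svy_prop()]
#'   columns.
#' @export
labor_status_distribution <- function(design, by = "period") {
  dat <- design$variables
  if (!by %in% names(dat)) abort_config(sprintf("grouping column '%s' not found", by))
  groups <- if (is.factor(dat[[by]])) levels(dat[[by]]) else sort(unique(dat[[by]]), method = "radix")
  statuses <- levels(dat$labor_status)
  out <- list()
  for (g in groups) {
    dom <- dat[[by]] == g
    if (!any(dom)) {
      warning(sprintf("no records in %s '%s'; omitted", by, g))
      next
    }
    for (s in statuses) {
      est <- svy_prop(design, dat$labor_status == s, domain = dom)
      est[[by]] <- g
      est$labor_status <- s
      out[[length(out) + 1]] <- est
    }
  }
  dplyr::bind_rows(out)[, c(by, "labor_status", "estimate", "se", "ci_low",
                            "ci_high", "n_unweighted", "n_weighted")]
}

#' Relative change between two prevalence estimates
#'
#' The signed percent change \eqn{100 (p_{end} - p_{start}) / p_{start}},
#' rounded to one decimal as reported in prevalence-trend text (e.g. a rise
#' from 26.7% to 33.7% is a +26.2% relative change).
#'
#' @param p_start Baseline percentage (> 0).
#' @param p_end Final percentage.
#' @return Signed percent change, one decimal.
#' @export
relative_change <- function(p_start, p_end) {
  if (any(p_start <= 0)) abort_domain("p_start must be positive")
  round1(100 * (p_end - p_start) / p_start)
}
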