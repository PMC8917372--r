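#' Model-adjusted prevalence (predictive margins) by subgroup
#'
#' For each cell of the grouping variables, the adjusted prevalence is the
#' weighted average of the model-fitted probabilities over the cell's
#' observed records (an average marginal prediction, not a prediction at
#' covariate means). Standard errors propagate the coefficient covariance by
#' the delta method: the gradient of a cell margin with respect to the
#' coefficients is the weighted average of \eqn{\hat p_i (1 - \hat p_i) x_i}
#' over the cell. Confidence intervals use the logit transform with t
#' critical values at the design degrees of freedom. Margins are invariant
#' to rescaling all weights by a constant.
#'
#' @param fit A converged [fit_survey_logit()] result.
#' @param by Character vector of grouping columns present in the model data
#'   (e.g. `c("period", "region")`).
#' @param level Confidence level.
#' @return A tibble: the grouping columns plus `estimate`, `se`, `ci_low`,
#'   `ci_high`, `n_unweighted`, `n_weighted`.
#' @export
adjusted_prevalence <- function(fit, by = c("period", "region"), level = 0.95) {
  stopifnot(inherits(fit, "svy_logit_fit"))
  dat <- fit$data
  missing_by <- setdiff(by, names(dat))
  if (length(missing_by) > 0) {
    abort_config(paste("grouping column(s) not found:", paste(missing_by, collapse = ", ")))
  }
  key <- interaction(dat[, by, drop = FALSE], drop = TRUE, sep = "\r", lex.order = TRUE)
  p <- fit$fitted
  w <- fit$weights
  tcrit <- qt(1 - (1 - level) / 2, df = max(fit$df, 1))

  out <- list()
  for (cell in levels(key)) {
    ing <- key == cell
    Wg <- sum(w[ing])
    m <- sum(w[ing] * p[ing]) / Wg
    grad <- drop(crossprod(fit$X[ing, , drop = FALSE],
                           w[ing] * p[ing] * (1 - p[ing]))) / Wg
    se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
    if (m > 0 && m < 1 && se > 0) {
      se_l <- se / (m * (1 - m))
      ci <- plogis(qlogis(m) + c(-1, 1) * tcrit * se_l)
    } else {
      ci <- c(m, m)
    }
    row <- stats::setNames(as.list(strsplit(cell, "\r", fixed = TRUE)[[1]]), by)
    out[[length(out) + 1]] <- tibble::as_tibble(c(row, list(
      estimate = m, se = se, ci_low = ci[1], ci_high = ci[2],
      n_unweighted = sum(ing), n_weighted = Wg)))
  }
  dplyr::bind_rows(out)
}
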