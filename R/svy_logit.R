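#' Survey-weighted logistic regression (pseudo-maximum likelihood)
#'
#' Fits a logistic regression by maximizing the weighted pseudo-log-likelihood
#' \deqn{\ell(\beta) = \sum_i w_i [y_i \log p_i + (1 - y_i) \log(1 - p_i)],
#'   \quad p_i = \mathrm{logit}^{-1}(x_i'\beta)}
#' with Newton--Raphson (step-halving on likelihood decrease, convergence on
#' the score norm). The coefficient covariance is the Taylor-linearized
#' sandwich under stratified cluster sampling: the bread is the inverse
#' weighted information, the meat the stratified between-PSU covariance of
#' the per-record score contributions \eqn{w_i (y_i - p_i) x_i}. With equal
#' weights and an independent-sampling design the estimates reduce to
#' ordinary maximum likelihood.
#'
#' Confidence intervals downstream use t critical values at the design
#' degrees of freedom (PSUs minus strata).
#'
#' @param formula Model formula with a 0/1 response.
#' @param design A [svy_design()] carrying the estimation sample; rows with
#'   missing values in model terms are an error (build the analytic sample
#'   first).
#' @param tol Convergence tolerance on the score norm (weights normalized to
#'   mean one), default 1e-8 scaled by the sample size.
#' @param maxit Maximum Newton--Raphson iterations.
#' @return An object of class `svy_logit_fit`: coefficients `beta`, sandwich
#'   `vcov`, fitted probabilities `fitted`, `df`, `converged`, `n_obs`, and
#'   the ingredients needed by [archer_lemeshow_gof()] and
#'   [adjusted_prevalence()].
#' @export
fit_survey_logit <- function(formula, design, tol = 1e-8, maxit = 50L) {
  stopifnot(inherits(design, "svy_design"))
  dat <- design$variables
  mf <- model.frame(formula, dat, na.action = stats::na.fail)
  constant <- vapply(mf[-1], function(v) {
    if (is.factor(v) || is.character(v)) length(unique(as.character(v))) < 2
    else FALSE
  }, logical(1))
  if (any(constant)) {
    abort_config(paste("constant factor term(s) in the estimation sample:",
                       paste(names(mf[-1])[constant], collapse = ", ")))
  }
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) abort_validation("response must be 0/1")
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X)
  if (length(unique(y)) < 2) {
    abort_domain("degenerate outcome: response is constant, model not estimable")
  }

  w <- dat[[design$weight_col]]
  wn <- w / mean(w)

  # collinearity check on the weighted design matrix
  qrX <- qr(X * sqrt(wn))
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort_config(paste("collinear model terms; candidate columns to drop:",
                       paste(dropped, collapse = ", ")))
  }

  loglik <- function(eta) {
    # numerically stable  sum wn * (y*eta - log(1 + exp(eta)))
    lse <- ifelse(eta > 30, eta, log1p(exp(eta)))
    sum(wn * (y * eta - lse))
  }

  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  eta <- drop(X %*% beta)
  ll <- loglik(eta)
  converged <- FALSE
  iters <- 0L
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    iters <- it
    p <- plogis(eta)
    score <- drop(crossprod(X, wn * (y - p)))
    if (sqrt(sum(score^2)) < tol * n) { converged <- TRUE; break }
    info <- crossprod(X * sqrt(wn * p * (1 - p)))
    step <- tryCatch(solve(info, score), error = function(e) {
      abort_validation("singular information matrix (quasi-separation or empty cells)")
    })
    # step-halving if the pseudo-likelihood does not improve
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      eta_new <- drop(X %*% beta_new)
      ll_new <- loglik(eta_new)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- beta_new; eta <- eta_new; ll <- ll_new
    trace <- c(trace, ll)
    if (max(abs(beta)) > 30) {
      worst <- names(beta)[which.max(abs(beta))]
      abort_validation(sprintf(
        "apparent separation: coefficient '%s' diverging (|beta| > 30)", worst))
    }
  }
  if (!converged) {
    stop(sprintf(
      "survey logit did not converge in %d iterations; pseudo-loglik trace: %s",
      maxit, paste(sprintf("%.4f", utils::tail(trace, 5)), collapse = " -> ")))
  }

  p <- plogis(eta)
  info <- crossprod(X * sqrt(wn * p * (1 - p)))
  bread <- solve(info)
  u <- X * (wn * (y - p))
  meat <- taylor_linearized_vcov(u, design_psu_keys(design), design$psu_frame)
  vcov <- bread %*% meat %*% bread
  dimnames(vcov) <- list(names(beta), names(beta))

  structure(list(
    beta = beta, vcov = vcov, fitted = p, y = y, X = X,
    weights = w, wn = wn,
    psu_keys = design_psu_keys(design), psu_frame = design$psu_frame,
    df = design$df, n_obs = n, converged = converged, iterations = iters,
    loglik = ll, formula = formula, data = dat
  ), class = "svy_logit_fit")
}

#' @export
print.svy_logit_fit <- function(x, ...) {
  cat(sprintf("Survey-weighted logistic fit: %d obs, %d terms, df = %d\n",
              x$n_obs, length(x$beta), x$df))
  cat(sprintf("  converged in %d iterations; pseudo-loglik (mean-one weights) %.3f\n",
              x$iterations, x$loglik))
  invisible(x)
}

#' Adjusted odds ratios with design-based confidence intervals
#'
#' Exponentiated coefficients with t-based 95% bounds at the design degrees
#' of freedom. When the model contains a sector-by-year interaction under
#' treatment coding, the `sectorpublic` aOR is the public-vs-private odds
#' ratio at the reference (first) survey year.
#'
#' @param fit A [fit_survey_logit()] result.
#' @param terms Coefficient names to report; default all.
#' @param level Confidence level.
#' @return A tibble: `term`, `beta`, `se`, `aor`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
adjusted_odds_ratios <- function(fit, terms = NULL, level = 0.95) {
  stopifnot(inherits(fit, "svy_logit_fit"))
  if (is.null(terms)) terms <- names(fit$beta)
  missing_terms <- setdiff(terms, names(fit$beta))
  if (length(missing_terms) > 0) {
    abort_config(paste("term(s) not in model:", paste(missing_terms, collapse = ", ")))
  }
  b <- fit$beta[terms]
  se <- sqrt(diag(fit$vcov))[terms]
  tcrit <- qt(1 - (1 - level) / 2, df = max(fit$df, 1))
  tstat <- b / se
  tibble::tibble(
    term = terms, beta = unname(b), se = unname(se),
    aor = exp(unname(b)),
    ci_low = exp(unname(b - tcrit * se)),
    ci_high = exp(unname(b + tcrit * se)),
    p_value = 2 * stats::pt(abs(unname(tstat)), df = max(fit$df, 1),
                            lower.tail = FALSE)
  )
}
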