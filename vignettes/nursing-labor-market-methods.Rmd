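---
title: "Measuring nursing labor-market performance from complex survey microdata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nursing labor-market performance from complex survey microdata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nursemkt)
```

## The problem

Professional labor markets for nurses are commonly judged by unemployment
alone, which is insensitive: trained nurses who cannot find health-sector
work mostly take jobs elsewhere rather than remain unemployed. `nursemkt`
implements a three-indicator view of market performance on repeated
cross-sections of a household labor-force survey:

* **unemployment** — economically active nurses not working for pay while
  available and seeking;
* **underemployment** (professional-market sense) — nurses working outside
  the health sector;
* **precarious employment** — an additive 0–5 score over five dichotomous
  adverse-employment indicators, for nurses who work.

The headline performance outcome is **non-precarious health-sector
employment**: a score of exactly zero while employed in the health sector.

The package targets microdata shaped like Mexico's quarterly ENOE survey
(a rotating household panel with five-visit cycles, stratum/PSU/expansion-
weight design variables, and an occupation catalogue identifying nurses),
but any file following the documented schema
(`system.file("extdata", "schema.csv", package = "nursemkt")`) works.

## The precariousness score

For a working nurse, each adverse condition contributes one point:

| component | flagged when | default threshold |
|---|---|---|
| salary | income at or below a multiple of the minimum wage | ≤ 2 × MW (boundary inclusive) |
| workday | part-time or extended hours | < 34 h or > 48 h (34–48 inclusive unflagged) |
| contract | no written contract | — |
| benefits | no social benefit at all | — |
| social security | no access to health-institution services | — |

The score is the unweighted sum; it is deliberately not a weighted index.
The `level` dichotomization (`non_or_low` vs `high`) needs a cut that the
indicator definitions do not themselves determine; the package defaults to
`high_cut = 3` — a majority of components adverse — and exposes it in the
configuration, since reasonable analysts could prefer 2 or 4. All
thresholds (salary multiple, hour band, cut) are printed into the run
metadata so a report is self-describing.

Boundary conventions follow a literal reading of the indicator definitions:
"up to two times the minimum wage" flags income equal to exactly 2 × MW,
while the hour band is open (exactly 34 or 48 hours is unflagged).

## Sample construction

`build_analytic_sample()` applies, in order: keep first-visit records only
(one-fifth of a rotating panel each quarter, removing the serial redundancy
of repeated visits), keep nurse occupation codes, keep the economically
active, and drop records with missing values among the required fields. The
audit object counts every stage. Two conventions matter:

* Employment fields of non-working (unemployed) nurses are *structural*
  blanks, not item nonresponse; the completeness rule checks employment
  fields only for working records, so unemployed nurses are retained for
  status distributions. They are excluded from both regression samples.
* Nurse occupation codes are configuration, not constants: real catalogues
  change across survey years. The package ships only its synthetic code set.

## Design-based estimation

All estimates respect the stratified cluster design. For a proportion the
estimator is the weighted ratio \(\hat p = \sum w_i y_i / \sum w_i\), with
variance from stratified between-PSU Taylor linearization of the ratio
estimator, and logit-scale confidence intervals using \(t\) critical values
at the design degrees of freedom (PSUs − strata). Subpopulation (domain)
estimates keep the full design: out-of-domain records contribute zero to the
linearized totals but every PSU stays in the between-PSU variance, which is
required for correct domain inference; simply subsetting rows would
understate the number of design units. Strata with a single PSU are an
error by default; an optional collapse rule merges singletons into the
preceding stratum for messy real data.

## The six regression models

The association between labor sector and non-precarious employment is
estimated with survey-weighted logistic regression,

\[
\log\frac{p}{1-p} = \beta_0 + \beta_{\text{sector}}\,\text{Sector}
 + \beta_{\text{trim}}\,\text{Trim} + \beta_{\text{survey}}\,\text{Survey}
 + \textstyle\sum_k \beta_k Z_k ,
\]

fitted by weighted pseudo-maximum likelihood (Newton–Raphson on the score,
tolerance \(10^{-8}\) scaled by the sample size, step-halving, at most 50
iterations; weights are normalized to mean one internally, which leaves the
coefficients and sandwich variance unchanged). The covariance is the
linearized sandwich with stratum/PSU clustering. Three nested levels are
fitted on each of two estimation samples (working nurses; health-sector
employees only): level 1 adjusts for quarter, survey year, sector and the
sector-by-year interaction; level 2 adds the individual covariates (sex,
age band, marital status, university education, number of jobs); level 3
adds residence and socioeconomic region.

Year and quarter enter as categorical factors. Because the model includes a
full sector-by-year interaction, a single "sector effect" is not defined
without a convention; the package uses treatment coding with the first
survey year as reference, so the reported sector aOR is the
public-vs-private odds ratio at the reference year. A pooled single aOR in
the presence of interaction cannot be reconstructed exactly and is not
attempted. Degenerate outcomes, separation (a coefficient diverging past
±30 on the logit scale) and collinear or sample-constant terms raise
explicit errors naming the offending term rather than returning a fragile
fit.

### Goodness of fit

`archer_lemeshow_gof()` implements the F-adjusted Hosmer–Lemeshow test for
complex samples: records are grouped into weighted deciles of the fitted
probability (stable sort, ties broken by record order), the design-based
group means of the raw residuals are tested jointly against zero with a
Wald statistic using their Taylor-linearized covariance (one group is
dropped — the weighted residuals sum to zero through the intercept score
equation), and the statistic is referred to
\(F(G-1,\, d-G+2)\) with \(d\) the design degrees of freedom.

A property worth knowing: because the residual covariance is estimated
ignoring the projection induced by estimating \(\beta\), the test grows
conservative as \(n\) increases at fixed \(G\): under a correct model the
rejection rate at \(\alpha = 0.05\) sits near 0.04 at \(n = 1{,}000\) (the
size at which the package's calibration test runs) and drifts below 0.03 by
a few thousand records. At large \(n\) the test errs on the side of not
rejecting.

### Adjusted prevalences

`adjusted_prevalence()` computes predictive margins: per period-by-region
cell, the weighted mean of the model-fitted probabilities over the cell's
*observed* records (an average marginal prediction, not a prediction at
covariate means), with delta-method standard errors through the sandwich
covariance and logit-scale intervals. Margins are invariant to rescaling
all weights.

## The synthetic generator and what passing tests mean

`simulate_enoe()` emulates the study conditions so every stage is testable
without external microdata: a five-visit rotating panel (exactly one fifth
of households at visit 1 each quarter; `visits = "first_only"` emits just
the rotation-in fifth, statistically identical for first-visit analyses),
32 strata × 6 PSUs, log-normal expansion weights with mean 250 (roughly the
persons-represented ratio of the study population to its sample),
covariate mixes chosen to resemble the published nurse population
(90% female, 75% aged 25–54, 70% of health-sector employees public), labor-
status probabilities interpolating the published 2005→2019 trend (stable 5%
unemployment, underemployment rising 26.7% → 33.7%), and item nonresponse
at 2% on the employment fields of working nurses.

The five precarity components are generated **independently given
covariates** from logistic models with known coefficients — an intercept, a
public-sector term, and a per-year trend each (defaults imply a
public-vs-private odds ratio of about 6.4 for the zero-score outcome at the
first study year, with slow secular deterioration). Independence is a
deliberate simplification: it makes the zero-score probability factorize,
so `expected_truth()` can compute exact ground truth by Monte Carlo
integration over the covariate distribution and parameter-recovery tests
have an oracle. Real components are correlated (informal jobs tend to lack
contract, benefits and social security together), so synthetic score
*distributions* are not calibrated to published score distributions — the
tests demonstrate correctness of the estimators, not realism of the joint
component law. Other features of real data the generator does not emulate:
serial correlation of a person's labor status across visits, calibration
(post-stratified) weighting, geographic clustering of sectors, and
occupation-catalogue changes over time.

The default problem size (20,000 households per quarter over 2005–2019,
2% nurse respondents, ≈ 4,600 analytic nurses) is a deliberately scaled-down
rendering of the national survey, chosen so a full pipeline run completes
in minutes on a laptop; the simulation studies in the test suite use
12-quarter windows with all-nurse sampling (≈ 20,000 employed records per
replicate) where the asymptotics, not the nurse fraction, are what is being
exercised.

## Numerical conventions

* Category orderings use locale-independent (radix) sorting, so runs are
  byte-reproducible across environments.
* Degenerate proportion estimates (0 or 1) return one-sided
  exact-binomial-style bounds instead of a zero-width interval.
* Rounding to one decimal happens only at render time; stored values keep
  full precision. Rendered five-column row percentages can drift from
  100.0 by up to ±0.25 (five independent roundings of ±0.05).
* All randomness flows from a single integer seed; regenerating with the
  same configuration is byte-identical, and a different seed changes
  records but not ground-truth summaries.

### Finite-sample behavior of the sandwich intervals

The linearized sandwich is the field-standard variance for survey-weighted
regression and is used here without small-sample corrections, as in the
major survey packages. Its known finite-cluster behavior carries over:
confidence intervals for contrasts that lean on a subset of the design
(such as the reference-year sector effect in the interaction model) run
slightly below nominal — the package's parameter-recovery simulations
observe coverage near 93–94% rather than 95% with 192 PSUs. Bias of the
point estimate is negligible at the simulated sizes.

## Known limitations

* The generator's independence-given-covariates assumption for the five
  components (above).
* The goodness-of-fit test's conservativeness at large \(n\).
* Replicate-weight (BRR/jackknife) variance and weight calibration are out
  of scope; variance is Taylor linearization only.
* The pipeline classifies underemployment structurally (working outside the
  health sector); survey questions about *preferring* other work are not
  used.
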