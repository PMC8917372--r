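# nursemkt

Design-based analysis of nursing labor-market performance from repeated
cross-sectional labor-force survey microdata.

## What it is for

Health-workforce researchers who want to measure, over many survey waves,
how well a professional nursing labor market performs: how many
economically active nurses are **unemployed**, how many are **underemployed**
(working outside the health sector — the professional-market sense of the
word), and how precarious the jobs of those who work are. Precariousness is
an additive 0–5 score over five dichotomous indicators:

| # | indicator | flagged when |
|---|-----------|--------------|
| 1 | salary | income ≤ 2 × minimum wage |
| 2 | workday | weekly hours < 34 or > 48 |
| 3 | contract | no written contract |
| 4 | benefits | no social benefit |
| 5 | social security | no access to health-institution services |

The headline outcome is **non-precarious health-sector employment** — a
score of exactly zero while employed in the health sector:

```
Log(p/(1−p)) = β₀ + β_sector·Sector + β_trim·Trim + β_survey·Survey + Σₖ βₖ Zₖ
```

fitted by survey-weighted pseudo-maximum likelihood with Taylor-linearized
(sandwich) variances under stratified cluster sampling, in three nested
levels on each of two estimation samples (six models), with an F-adjusted
Hosmer–Lemeshow (Archer–Lemeshow) goodness-of-fit test and model-adjusted
prevalences (predictive margins) by period and socioeconomic region.

The package targets microdata shaped like Mexico's quarterly ENOE survey
(rotating five-visit household panel, stratum/PSU/expansion-weight design),
via a documented columnar schema
(`system.file("extdata", "schema.csv", package = "nursemkt")`).
A synthetic generator, `simulate_enoe()`, emulates that design with known
ground-truth parameters so the whole pipeline is testable end to end
without external data.

## Worked example

```r
library(nursemkt)

# a small synthetic run: 4,000 households/quarter over 2005-2008,
# half of respondents nurses, first-visit records only
cfg <- run_config(params = sim_params(
  n_households_per_quarter = 4000,
  quarters = quarter_grid(2005:2008),
  nurse_fraction = 0.5, visits = "first_only", seed = 4242))
res <- run_pipeline(cfg, out_dir = "report", quiet = TRUE)

print(res$audit)
#> Analytic-sample audit
#>   raw records               12800
#>   first-visit records       12800
#>   econ-active nurses         6149
#>   complete (analytic)        6035
#>   excluded incomplete         114

adjusted_odds_ratios(res$models$employed_only_m3, "sector_fpublic")
#> # A tibble: 1 x 7
#>   term            beta    se   aor ci_low ci_high  p_value
#>   <chr>          <dbl> <dbl> <dbl>  <dbl>   <dbl>    <dbl>
#> 1 sector_fpublic  1.64 0.156  5.17   3.80    7.03 4.47e-20

res$gof$employed_only_m3
#> F-adjusted Hosmer-Lemeshow (Archer-Lemeshow) test: F(9, 152) = 0.499, P > F = 0.874
```

Reading the output: of 12,800 generated person-quarter records, 6,149 are
first-visit economically active nurses and 6,035 survive the completeness
rule (the audit mirrors the stagewise construction of a real analytic
sample). In the most-adjusted model on health-sector employees, public-
sector nurses have about 5 times the odds of a non-precarious job relative
to private-sector nurses at the reference year — the generator's known
protective public-sector effect, recovered from the simulated survey — and
the goodness-of-fit test does not reject the model. `report/` contains the
machine-readable tables: the status-distribution series, the weighted
characteristics cross-tabulation, precarity-level series by sector, the
six-model summary, adjusted prevalences by period and region, and the
headline relative changes.

A thin CLI over the same functions ships at
`system.file("scripts", "nursemkt-cli.R", package = "nursemkt")` with
subcommands `simulate | classify | score | estimate | fit | report | run-all`.

## Package layout

- `R/` — generator (`simulate_enoe`, `expected_truth`), cohort rules
  (`build_analytic_sample`, `classify_labor_status`, `assign_period`),
  scoring (`precarity_components`, `add_precarity`), design-based
  estimation (`svy_design`, `svy_prop`, `labor_status_distribution`),
  models (`fit_survey_logit`, `adjusted_odds_ratios`,
  `archer_lemeshow_gof`, `adjusted_prevalence`) and the pipeline
  (`run_config`, `run_pipeline`, `render_tables`).
- `vignettes/nursing-labor-market-methods.Rmd` — the methods vignette:
  model, assumptions, thresholds, generator design, numerical conventions,
  limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests; all
  fixtures are built in code.
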