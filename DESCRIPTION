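Package: nursemkt
Title: Design-Based Analysis of Nursing Labor-Market Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the performance of a professional nursing labor
    market with repeated cross-sectional labor-force survey microdata. Classifies
    economically active nurses into unemployment, underemployment (working outside
    the health sector) and health-sector employment; computes a five-component
    additive precariousness score (salary, workday, written contract, social
    benefits, social-security health access) and the non-precarious-employment
    outcome; estimates design-based weighted prevalences with Taylor-linearized
    variances under stratified cluster sampling; and fits nested survey-weighted
    logistic regression models with sandwich variances, adjusted odds ratios,
    an F-adjusted Hosmer-Lemeshow (Archer-Lemeshow) goodness-of-fit test and
    model-adjusted prevalences. A synthetic microdata generator emulating a
    rotating-panel household survey (in the style of Mexico's ENOE) with known
    ground-truth parameters makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
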