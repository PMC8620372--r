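Package: oevax
Title: Observed-Versus-Expected Projection of Post-Vaccination Adverse
    Events from Claims-Based Background Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for observed-versus-expected pharmacovigilance analyses
    of post-vaccination adverse events. Estimates background incidence rates
    of venous thromboembolism (VT) and immune thrombocytopenia (ITP) from a
    person-level cohort using ICD-9-CM hospital-discharge case definitions
    (first-occurrence rule, pre/post-2007 coding dialect), computes stratified
    person-time by Lexis expansion across attained-age bands, derives
    incidence rates with log-normal 95% confidence intervals, projects the
    expected number of events in a fixed post-vaccination risk window onto a
    dose table stratified by gender and age band, and quantifies projection
    uncertainty with Poisson-bootstrap prediction intervals. Includes a
    synthetic-cohort generator with known ground-truth hazards so the whole
    pipeline is testable without access to restricted claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
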