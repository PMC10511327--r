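Package: wastingepi
Title: Longitudinal Analysis of Child Wasting Episodes in Birth Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the longitudinal epidemiology of child wasting
    (weight-for-length z-score below -2) in the first 24 months of life.
    Classifies discrete wasting and severe-wasting episodes from monthly
    anthropometry z-score series using midpoint onset/recovery conventions
    and a configurable washout period; computes person-time at risk,
    incidence rates, recovery proportions, episode durations, age-stratified
    prevalence, cumulative incidence, persistent wasting, concurrent
    wasting-stunting, and growth-faltering state partitions; pools
    cohort-specific estimates with two-stage random-effects meta-analysis;
    relates weight-for-length z-scores to rainfall seasonality via the
    Walsh-Lawler seasonality index; and quantifies regression-to-the-mean in
    threshold-selected groups. Includes a synthetic longitudinal cohort
    generator with known ground truth so every pipeline stage can be
    exercised without access-controlled study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
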