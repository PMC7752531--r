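Package: ilisurv
Title: Participatory Influenza-Like Illness Surveillance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mobile participatory influenza-like
    illness (ILI) surveillance cohorts: study-week calendar arithmetic with a
    system-maintenance window, typed CSV readers for participant rosters,
    weekly symptom reports and sentinel reference series, participation
    metrics (individual submission rates, weekly reporting rates,
    committed-user classification) with multivariable covariate models and
    marginally standardized adjusted rates, weekly ILI incidence with
    within-week report deduplication and consecutive-week episode
    consolidation, trailing moving proportions, and surveillance-power
    estimation as Pearson correlation against a sentinel reference series,
    overall and stratified by participant characteristics. A seeded
    synthetic-cohort generator emulates the statistical structure of such
    studies (covariate-dependent adherence, a post-disruption participation
    drop, within-week duplicate submissions, and ILI onset hazard coupled to
    the reference series) so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
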