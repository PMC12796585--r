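Package: ehrconsult
Title: Cohort Analytics and Informatics Consults for Event-Level EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale clinical analytics toolkit for de-identified,
    event-level electronic health record data. Provides a common data model
    for coded clinical events stored as Parquet tables, a declarative
    computable-phenotype cohort engine with per-patient index dates, a
    synthetic EHR generator with known ground truth, a library of analytics
    modules (demographics overviews, patient-level event frequency,
    relative-risk comorbidity scans, Kruskal-Wallis value comparison,
    Kaplan-Meier time-to-event) with small-cell suppression throughout, and
    a GAMLSS-style reference-model engine that fits sinh-arcsinh or logistic
    distributions with P-spline smoothed parameters over time since cohort
    entry and scores an individual patient against a comparator cohort via
    centiles and z-scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
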