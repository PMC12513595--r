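Package: pvsignals
Title: Disproportionality Signal Mining for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection from
    FAERS-style and JADER-style spontaneous adverse-event reports: reading
    both file dialects into a normalized case model, case deduplication,
    suspect-drug selection, drug-event 2x2 contingency tables at MedDRA
    preferred-term and system-organ-class level, and four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio with
    Yates chi-squared, the BCPNN information component with its closed-form
    credibility bound, and the DuMouchel gamma-Poisson shrinker EBGM with
    empirical-Bayes hyperparameter fitting) combined into a conjunctive
    positive-signal flag. Includes descriptive profiling (demographics,
    annual and organ-class distributions, time-to-onset, tumor versus
    non-tumor indication strata) and a synthetic spontaneous-report
    generator with known ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vctrs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
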