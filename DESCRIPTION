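Package: couplingprior
Title: Coupling-Prior Analysis of Hand-Cursor Sensory Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing partial sensory integration in cursor-control
    experiments. Implements the coupling-prior model of reliability-weighted
    cue combination, trial-level bias regressions that estimate sensory
    weights and integration strength from position judgments, the outlier
    screening and response-hysteresis correction used in such experiments,
    a seeded synthetic-trial generator with known ground truth for parameter
    recovery studies, and group-level repeated-measures statistics
    (paired t-tests, two-way within-subject ANOVA, Pearson correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite
Suggests:
    ggplot2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
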