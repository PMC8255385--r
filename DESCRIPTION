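Package: groupitizr
Title: Auditory Groupitizing Stimuli, Synthetic Observers, and
    Estimation-Precision Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying groupitizing in audition: schedules and
    renders 1.4-s tone sequences (numerosities 5-12) that are unstructured,
    grouped by tone frequency, or grouped by inter-stimulus interval;
    simulates cohorts of Weber-law observers with condition-specific
    precision; and analyses trial tables end-to-end with 3-SD outlier
    exclusion, per-cell coefficients of variation (CV = sigma/N), grouping
    advantage, fully within-subject repeated-measures ANOVA with partial
    eta squared, paired t-tests with Bonferroni correction and Cohen's d,
    and default (JZS) Bayes factors reported as base-10 logarithms.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
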