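Package: ohtcohort
Title: Analysis Pipeline for Chronic Ocular Hypertension Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping rodent chronic ocular hypertension studies
    with bilateral (treated vs. contralateral control) designs. Decomposes
    dark-adapted full-field electroretinograms into photoreceptoral (P3,
    delayed-Gaussian model), ON-bipolar (P2, Naka-Rushton intensity-response),
    oscillatory-potential (zero-phase 50-180 Hz band-pass) and ganglion-cell
    (positive scotopic threshold response) measures; summarizes longitudinal
    rebound tonometry (baseline, post-surgical spike, chronic plateau);
    computes OCT and flat-mount morphometry (RNFL and total retinal thickness,
    Bruch's membrane opening, minimum rim thickness, Doppler pixel flow,
    ganglion cell density); performs absolute qPCR quantification against
    external standard curves with housekeeping normalization; and assembles
    the cohort statistics (paired and unpaired t-tests, two-way repeated
    measures ANOVA, assumption screening, percent change, attrition
    accounting). A synthetic-cohort generator with known ground truth drives
    validation of every stage.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
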