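Package: ivdd
Title: Outcome Analysis for Ovine Annular-Lesion Models of Intervertebral
    Disc Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for preclinical intervertebral disc
    degeneration studies built around the ovine annular-lesion model:
    torque-angle biomechanics (range of motion, gradient-threshold neutral
    zone and initial stiffness from seventh-order polynomial fits of
    hysteresis loops), disc height index radiogrammetry from landmark
    coordinates, cumulative ordinal histopathology scoring with
    two-observer reconciliation, standard-curve quantitation of sulfated
    glycosaminoglycan and hydroxyproline, total-RNA-normalized qPCR
    relative copy numbers, and exact Mann-Whitney U comparisons with
    Benjamini-Hochberg correction. A calibrated synthetic-study generator
    reproduces the cohort structure of a mesenchymal-stem-cell treatment
    experiment (early acute, late acute and established lesion groups with
    PBS and MSC arms against nonoperated controls) so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
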