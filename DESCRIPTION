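Package: radcourse
Title: Longitudinal Multi-Endpoint Analysis of Irradiated Primate Blood
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analyzing longitudinal blood endpoints after acute
    total-body irradiation in non-human primates. Implements a kinetic model
    family for micronucleus frequency time courses (production-decay curves
    fitted by SEM-weighted nonlinear least squares with AIC model selection
    and a random-intercept mixed-effects variant), two-proportion tests for
    per-animal micronucleus comparisons, hematology time-course
    characterization (baseline, paired tests, percent change, nadir and
    recovery days), differential-molecule calling with Benjamini-Hochberg or
    permutation-based FDR control, multi-timepoint and cross-modality list
    overlap with a time-correlation filter, and hypergeometric gene-set
    overrepresentation against GMT collections. A seeded synthetic-data
    module generates micronucleus tables, cell-count trajectories, molecule
    lists and expression matrices with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
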