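Package: ccastab
Title: Split-Half Stability Assessment for Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the stability of canonical correlation
    analysis (CCA) between two high-dimensional variable sets, such as
    brain-imaging measures and behavioral subject measures.  Implements
    pseudorandom split-half resampling with an exactly controlled number of
    overlapping subjects, PCA dimension reduction with double
    standardization, first-mode CCA with permutation significance, bootstrap
    significance of canonical loadings, projection of canonical weights onto
    held-out subjects, and three stability assessments (similarity of
    canonical correlation coefficients, consistency of statistical
    significance, and correlation of loading vectors) aggregated over grids
    of data dimensionality (subject-to-variable ratio) and subject-overlap
    rates.  Includes a synthetic-data generator with an analytically known
    population canonical structure and quality-control defect fixtures, plus
    quality-control filters for missing-data and low-variance variables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
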