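Package: biodoseilc
Title: Dicentric-Chromosome Dose Estimation and Interlaboratory Comparison Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cytogenetic biological dosimetry based on the dicentric
    chromosome assay. Fits linear-quadratic dose-effect (calibration) curves to
    per-dose dicentric count distributions by identity-link Poisson maximum
    likelihood, inverts them to dose estimates with 95% confidence intervals
    (Merkle-style combination of exact Poisson yield limits with the
    calibration-curve error, or yield-error-only), computes the dispersion
    index and Papworth U-test for departure from Poisson scoring, converts
    between air-kerma and dose-to-blood dose definitions, and scores blinded
    interlaboratory comparisons (Z-scores, systematic-bias classification,
    triage categories, band and ranking checks). A synthetic-data generator
    reproduces the statistical structure of a multi-laboratory exercise so the
    whole chain is testable end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
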