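Package: twosmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and validating summary tables, allele harmonization
    with palindromic-variant handling, instrument selection (genome-wide
    significance, windowed LD clumping, outcome-association exclusion,
    F-statistic gating, variance explained), causal-effect estimation by
    inverse-variance-weighted meta-analysis, weighted median, and MR-Egger
    regression, sensitivity diagnostics (Cochran's Q and I-squared, a
    simulation-based pleiotropic-outlier test, leave-one-out, funnel data),
    binary-outcome power calculation, and a calibrated synthetic
    summary-statistics generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
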