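Package: gwasmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("GWAS", "MR Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and validating summary-association tables, harmonizing
    exposure and outcome effect alleles (strand flips, palindromic variants,
    file-based proxy substitution), instrument-strength diagnostics (F
    statistics, I-squared for the NOME assumption, variance explained, power
    for binary outcomes), pleiotropy-robust univariable estimators
    (inverse-variance weighted with multiplicative random effects, weighted
    median, MR-Egger), multivariable MR with Sanderson-Windmeijer conditional
    F and a modified Q statistic, a synthetic summary-statistics generator
    with known ground truth for estimator calibration, and a configurable
    study pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
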