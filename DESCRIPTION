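Package: mrmediate
Title: Two-Sample Mendelian Randomisation with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomisation (MR) workflow for
    GWAS summary statistics: instrument selection with greedy LD/distance
    clumping, exclusion filtering (confounder blacklists, palindromic
    variants), effect-allele harmonisation, a battery of univariable
    estimators (fixed- and random-effect inverse-variance weighted, MR-Egger,
    weighted and penalised weighted median, maximum likelihood, radial IVW,
    SIMEX-corrected IVW, MR-PRESSO), multivariable MR (IVW, Egger, Q-minimising
    QHET), and two-step MR mediation with delta-method confidence intervals,
    Sobel tests and proportion mediated. Method choice follows a
    pleiotropy-then-heterogeneity decision tree, and families of tests are
    tiered by Benjamini-Hochberg false-discovery-rate control. A synthetic
    summary-statistics generator under an exposure-mediator-outcome causal
    DAG provides ground truth for calibration and benchmarking.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
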