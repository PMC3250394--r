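Package: quantpen
Title: Quantile-Dependent Penetrance Analysis of Genetic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing whether the phenotypic effect of a genetic
    risk score (GRS) depends on the population percentile of the phenotype
    ("quantile-dependent penetrance"). Builds weighted allele-dosage risk
    scores from published per-allele effects or sample-fitted weights,
    residualizes phenotypes and scores on covariates, estimates the slope of
    phenotype on score at every percentile by quantile regression with
    paired-bootstrap standard errors and covariances, tests for a linear
    trend of the slope across percentiles, and computes the proportion of
    variance explained under quantile-specific slopes by projection to the
    mean score. Includes a heteroscedastic location-scale cohort simulator
    with known genetic architecture for validation, and a residual
    permutation null check.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
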