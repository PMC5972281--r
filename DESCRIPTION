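Package: cfasim
Title: Monte Carlo Evaluation of One-Factor Confirmatory Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how well one-factor confirmatory
    factor analysis (CFA) recovers population loadings under small to moderate
    sample sizes, model sizes and loading magnitudes. Generates multivariate
    normal samples from a known unifactorial population model, fits the model
    by maximum likelihood (to the sample covariance matrix) or unweighted
    least squares (to the sample correlation matrix) with the factor variance
    fixed to one, screens improper solutions (nonconvergent fits and Heywood
    cases), and evaluates parameter recovery with Tucker's coefficient of
    congruence against the chi-square test, RMSEA and CFI. Includes
    positive-definiteness and Mahalanobis-distance outlier diagnostics, a
    full study driver with per-replication reproducibility, and pooled
    summary tables of proper-solution rates, average loadings, congruence
    and fit indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
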