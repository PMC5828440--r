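Package: nbclustsim
Title: Data Transformations and Gaussian Model-Based Clustering of RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for assessing how data transformations
    (naive, log2, Blom rank-normal, variance stabilizing) affect Gaussian
    model-based clustering of RNA-Seq count data. Fits per-gene negative
    binomial maximum likelihood parameters to a count matrix, simulates
    clustered count datasets under controlled effect-size shifts, applies
    the four transformations, clusters samples with a diagonal-covariance
    Gaussian mixture model selected by BIC, and scores normality (skewness,
    excess kurtosis) and partition recovery (adjusted Rand index,
    clustering error rate, concordance index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    readxl,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
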