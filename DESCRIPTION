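Package: mtgp
Title: Multi-Trait Genomic Prediction and Corrected Accuracy Estimation for Two-Cycle Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian single- and multi-trait genomic best linear unbiased
    prediction (GBLUP) via a matrix-variate Gibbs sampler, with marker quality
    control, VanRaden genomic relationship matrices, and the corrected
    prediction-accuracy estimators PC1-PC4 (heritability-corrected Pearson
    correlations and a bivariate variance-component estimator) evaluated in a
    two-cycle breeding-program cross-validation. Includes a synthetic
    wheat-breeding data generator with known true breeding values so that the
    bias of each accuracy estimator is directly measurable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
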