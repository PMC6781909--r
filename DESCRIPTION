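Package: gblupvar
Title: Best Prediction of the Additive Genomic Variance in Random-Effects
    Marker Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits the genomic best linear unbiased prediction (gBLUP) model
    y = mu + g + e with g ~ N(0, sigma_g^2 G) by spectral profile restricted
    maximum likelihood, and predicts the random additive genomic variance
    s_g^2 = beta' SigmaHat_X beta by its conditional expectation (best
    predictor, W) alongside the classical unconditional-expectation
    estimators (V, the GREML convention).  Both the current and the base
    population are supported, together with an exact decomposition
    W = V + L(y) isolating the contribution of linkage disequilibrium to
    the genomic variance.  Includes a Bayesian ridge regression Gibbs
    sampler whose posterior-mean variance (M2) serves as an independent
    cross-check of the closed-form best predictor, simulators for marker
    genotypes with tunable minor-allele-frequency spectrum and
    adjacent-marker LD, and readers for delimited genotype/phenotype files
    and PLINK .raw exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
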