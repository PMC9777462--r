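Package: labsieve
Title: Predictive Analyte Selection from Sparse Laboratory Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens hospital laboratory analytes for predictive value with
    respect to a binary diagnosis (the motivating case is myocardial
    ischemia labelled from ICD-10 codes) when the case-by-analyte matrix is
    sparse. Provides sparsity-tiered analyte subsetting, multiple imputation
    by chained Bayesian regressions with Gelman-Rubin convergence
    monitoring, Bayesian model averaging over probit models via an
    orthogonal-data-augmentation Gibbs sampler with Rao-Blackwellized
    posterior inclusion probabilities, Occam's window model pruning,
    cross-chain pooling of inclusion probabilities with confidence
    intervals and a "highly predictive" classification rule, an exact
    enumeration oracle for validating the sampler, and a synthetic cohort
    generator emulating skewed laboratory value distributions, tiered
    missingness, and a derived CKD-EPI eGFR analyte.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
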