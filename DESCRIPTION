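Package: nigreg
Title: Normal Inverse Gaussian Shrinkage Regression with External Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-response linear regression with normal inverse Gaussian
    (NIG) global-local shrinkage priors, designed for drug sensitivity
    prediction from high-dimensional molecular features.  Prior means of the
    local (feature-level) and global (drug-level) variance components are
    modelled as functions of external covariates (co-data) and estimated by
    empirical Bayes within a variational Bayes EM algorithm.  Includes
    numerically stable generalized inverse Gaussian moment computations via
    modified Bessel function ratios, a Gibbs sampler for validating the
    variational approximation, a simulator for the generative model,
    cross-validated prediction error, and decoupled
    shrinkage-and-selection sparse summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
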