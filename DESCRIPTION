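Package: envmed
Title: Sparse Envelope Partial Least Squares for Causal Mediation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint estimation of direct and indirect causal effects with
    multivariate exposures, high-dimensional mediators and multivariate
    outcomes using the envelope-based sparse partial least squares mediation
    model (ESPLSM). The mediator covariance is decomposed into material and
    immaterial parts via a predictor envelope; an adaptive group lasso on the
    rows of the envelope basis selects outcome-relevant mediators; all
    regression parameters then have closed forms. The package provides
    Grassmann-manifold optimization of the envelope objective, cross-validated
    dimension selection, sparse permutation-invariant covariance (SPICE)
    surrogates for the p > n regime, asymptotic (Wald) and nonparametric
    bootstrap inference for the average natural direct effect and the average
    causal mediation effect, a simulation engine with known ground truth, and
    benchmarking utilities (Frobenius RMSE, selection metrics, empirical
    power).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
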