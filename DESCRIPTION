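Package: cmmael
Title: Categorical Marginal Models for Large Sparse Contingency Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Specification and constrained maximum-likelihood estimation of
    categorical marginal models (CMMs) of the form B'f(A'm) = 0 on multinomial
    expected frequencies, using a sparse support representation so that models
    on contingency tables far too large to materialize (e.g. 2^40 cells) can be
    fitted, tested and simulated.  Implements maximum likelihood (ML), maximum
    empirical likelihood (MEL) and maximum augmented empirical likelihood
    (MAEL) estimation by Aitchison-Silvey/Lang-style Fisher scoring on the
    Lagrangian; detection of the first-order (empty-set) and second-order
    (singular marginal covariance) estimation problems; model builders for
    marginal homogeneity / equality of item means, Cronbach's alpha benchmark
    tests and Mokken item-scalability coefficients H_j; and a simulation
    harness with two-parameter logistic (2PL) null populations for convergence
    and Type I error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    boot,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
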