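Package: dosem
Title: Interventional Distributions and Causal Inference for Linear
    Structural Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Linear Gaussian causal models on acyclic directed mixed
    graphs (ADMGs) with directed edges (path coefficients) and
    bidirected edges (correlated errors).  Implements the do-operator
    in closed matrix form: interventional means, (singular)
    interventional covariance matrices, densities and interval
    probabilities; average treatment effects; the contrast between
    conditional and interventional distributions; and optimal
    single-dose intervention search.  Model parameters are estimated
    by covariance-based maximum likelihood, and causal quantities
    receive delta-method asymptotic standard errors, z-values and
    confidence intervals via closed-form Jacobians of the causal
    effect functions.  Includes a seeded simulator for observational
    and interventional data and a built-in six-variable
    insulin-glucose panel example.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mvtnorm,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
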