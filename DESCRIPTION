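Package: tumgrowth
Title: Population Modelling of Preclinical Tumour Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of preclinical (mouse
    orthotopic / syngeneic) tumour-growth experiments. Implements a
    generalized Gompertz structural growth model with a multiplicative
    treatment effect on the growth rate, nonlinear mixed-effects
    estimation of its population parameters by stochastic approximation
    EM (SAEM), importance-sampling evaluation of the observed-data
    log-likelihood, likelihood-ratio testing of treatment-arm covariates,
    and simulation-based prediction intervals. Also provides a synthetic
    cohort simulator emulating a caliper-measured in vivo study design,
    Hill-equation fitting of normalized concentration-response data, and
    the Gehan-Breslow-Wilcoxon weighted log-rank test with an exact
    permutation option.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
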