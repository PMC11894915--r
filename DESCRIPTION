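Package: nbvoi
Title: Value of Information for External Validation of Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-theoretic sample size reasoning for external validation
    studies of clinical risk prediction models. Computes net benefit (NB) for
    the three classification strategies (treat none, use the model, treat all)
    at a risk threshold, and the expected value of perfect information (EVPI)
    and of sample information (EVSI) for a planned validation sample, in net
    true-positive or false-positive units. Three Monte Carlo algorithms are
    provided: a two-level Bayesian (Dirichlet-weight) or ordinary bootstrap for
    individual-level pilot data, a fast conjugate beta-binomial algorithm for
    independent beta posteriors on prevalence, sensitivity and specificity,
    and a general likelihood-reweighting algorithm for arbitrary posterior
    draws. Includes decision curves with percentile-bootstrap intervals,
    population scaling of value-of-information estimates, and a synthetic
    validation-sample generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
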