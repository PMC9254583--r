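Package: disinfopt
Title: Neural Network Modeling and Multi-Objective Optimization of Explant Disinfection Protocols
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the outcome of plant tissue culture surface-disinfection
    experiments with a 4-10-2 multilayer perceptron (tansig hidden layer,
    linear output) and searches for Pareto-optimal protocols with a
    real-coded multi-objective genetic algorithm. Ships the published
    weight matrices and 28-treatment experiment table from a pistachio
    (Pistacia vera) seed disinfection study, reproduces the published
    predictions and error metrics, retrains the network from scratch with
    Levenberg-Marquardt backpropagation and validation-based early
    stopping, and generates synthetic dose-response experiment tables for
    end-to-end pipeline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
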