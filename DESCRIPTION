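Package: redmotor
Title: Learning Speed in Redundant Motor-Cortex Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and closed-form theory for trial-by-trial motor
    adaptation in linear rate networks with redundant neural populations.
    Provides decoder sampling under uniform, Gaussian and high-dimensional
    families, gradient-descent and weight/node-perturbation learning rules
    with synaptic decay and drift, eigenvalue analysis of the learning
    operator, analytic learning curves, generalization via cosine and von
    Mises input tuning, and experiment orchestration (baseline plus
    rotation-perturbation phases, exponential speed fits, paired
    nonparametric comparisons) for studying how the gap between neuron
    count and task count sets learning speed, stability and residual error.
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
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
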