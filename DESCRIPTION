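Package: vagaltrace
Title: Cytokine-Evoked Calcium Transient Analysis for Vagal Sensory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for cytokine-evoked calcium activity in vagal
    (nodose ganglion) sensory neurons recorded by in vivo miniscope imaging.
    Detects calcium transients in DFF traces, extracts six response features
    (amplitude, duration, rise slope, decay slope, integral, number of peaks),
    assigns transients to cytokine applications under a 100-second response
    window, classifies neurons into responder subpopulations, quantifies
    spontaneous baseline activity, and measures the separability of cytokine
    response clusters with Tukey-fence outlier removal, iterative cross-group
    nearest-neighbor pruning, the Calinski-Harabasz index, and a permutative
    Mann-Whitney test. A seeded synthetic-data generator produces populations
    of DFF traces with known ground truth under control and colitis-like
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
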