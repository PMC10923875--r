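Package: brainflex
Title: Whole-Brain Coupled-Oscillator Simulation and Network Flexibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-brain dynamics as a network of FitzHugh-Nagumo
    oscillators coupled through a weighted structural connectome and driven
    by a block-design square-wave input mimicking an N-back working-memory
    task. Neural activity is transformed to BOLD-like signals with the
    Balloon-Windkessel hemodynamic model, summarized as sliding-window
    Pearson functional connectivity matrices, and characterized by two
    dynamic network reconfiguration measures: template flexibility (change
    of a-priori module affiliations between consecutive windows) and
    distance flexibility (Pearson distance between consecutive functional
    matrices). Includes a synthetic modular connectome generator, an
    edge-weight shuffle null model, stimulated-node selection by weighted
    degree, ensemble experiment orchestration and comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
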