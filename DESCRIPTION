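Package: emgforce
Title: Motor Unit Pool Simulation and Log-Transformed EMG-Force Slope Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates surface electromyography (EMG) and isometric force from a
    motor neuron pool model with configurable motor unit depth distributions
    (superficial, random, deep), synthesizes surface potentials through an
    anisotropic volume conductor using a travelling tripole source model, and
    quantifies the EMG-force relation by the slope b of the log-transformed
    regression ln(RMS) = b ln(force) + ln(a). Includes per-channel slope maps
    for high-density electrode grids, regional comparisons with nonparametric
    paired statistics, a synthetic grid-session generator emulating isometric
    contraction protocols, and end-to-end study runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    data.table,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
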