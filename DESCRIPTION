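Package: microlink
Title: Simulated Optical Interlink Feedback Between Two Microalgal Micro-Aquaria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based twin of a closed-loop optical interlink experiment in
    which two isolated 25-square micro-aquaria, one holding photophobic
    Euglena gracilis-like swimmers and one holding photo-activated
    Chlamydomonas reinhardtii-like swimmers, are coupled only through
    exchanged trace-momentum (TM) data and a feedback algorithm. Provides the
    5x5 chamber geometry, stochastic run-and-tumble cell models, binary
    trace-image rasterization with per-square pixel counting, the two-state
    flipping and ranking feedback algorithms, analysis of oscillation period,
    phase delay, illumination coincidence, duty ratios and grid clustering,
    and calibration of the free behavioral parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
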