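Package: spheroidax
Title: Conduction Through Spheroid-Bearing Axons and Functional-Imaging Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Compartmental Hodgkin-Huxley cable simulation of axons bearing
    plaque-associated axonal spheroids (modelled as a bulb-and-neck side
    branch acting as a capacitive current sink), with sweep and
    conduction-regime classification tools; calcium-trace analysis
    (deltaF/F, exponential rise-time spike-timing estimation, ROI-pair
    delays); voltage line-scan kymograph analysis (stimulation-locked dip
    detection, 10 Hz FFT power, logistic stimulation-threshold fitting);
    cortical population-activity statistics (spike inference, pairwise
    mutual information by distance, deterministic community detection,
    subsampled population entropy); and seeded synthetic-data generators
    that emulate every input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
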