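Package: megpli
Title: Atlas-Based MEG Beamformer Source Reconstruction and Phase-Based
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs region-of-interest (ROI) source time-series from
    multichannel magnetoencephalography (MEG) recordings with a scalar
    (SAM-style) minimum-variance beamformer over an analytic spherical head
    model, and estimates frequency-band specific functional connectivity
    between ROIs with the Phase Lag Index (PLI), an estimator insensitive to
    volume conduction and beamformer field spread, alongside the classical
    Phase Coherence reference estimator. Significance of node-strength
    (weighted degree) maps is assessed with a phase-randomised surrogate
    null using max-statistic family-wise error control. A seeded forward
    simulator of coupled narrowband dipole sources in a conducting sphere
    provides fully synthetic test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    signal,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
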