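Package: sslspectra
Title: Forward Acoustic Modeling and Broadband Spectral Analysis of Sound
    Scattering Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physics-based target-strength models for the three acoustic
    scatterer classes found in mixed sound scattering layers (fluid-like
    zooplankton via the distorted-wave Born approximation, elastic-shell
    pteropods via a high-pass dense-fluid sphere, and gas-bearing organisms
    via a damped resonant prolate-spheroid bubble model), forward prediction
    of volume-backscattering spectra from net-sample tables, Latin hypercube
    propagation of scattering-parameter uncertainty into spectral confidence
    envelopes, expectation-maximization segmentation of broadband echograms,
    and a synthetic-data generator for closed-loop validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    lhs,
    mclust,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
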