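Package: speckleflow
Title: Simulation of Diffuse Correlation and Speckle Contrast Blood Flow Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models, instrument models, and noise models for comparing
    diffuse correlation spectroscopy (DCS) and speckle contrast optical
    spectroscopy (SCOS) measurements of cerebral blood flow. Includes a
    layered-slab dynamic light scattering Monte Carlo generating per-photon
    partial pathlength and momentum-transfer histories, semi-infinite
    correlation diffusion theory, a correlation-function noise model, a
    dynamic speckle simulator, photon timestamp generation with detector dead
    time and a multi-tau software correlator, blood flow index inversion for
    both modalities, and a performance pipeline computing cerebral
    sensitivity, coefficient of variation, and contrast-to-noise ratio across
    operating conditions (source-detector separation, fitting range, exposure
    time, laser delivery strategy, detected mode count, extracerebral
    thickness).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
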