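Package: acoustopiv
Title: Particle Image Velocimetry Analysis of Acousto-Mechanically
    Modulated Microchannel Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Digital particle image velocimetry (DPIV) pipeline for
    micro-particle videos recorded in microfluidic channels under
    ON-OFF acousto-mechanical stimulation. Provides multi-pass FFT
    cross-correlation with sub-pixel Gaussian peak fitting and
    normalized-median vector validation, time-domain velocity-range
    and frequency-domain peak and band-integral response metrics,
    stimulation-protocol utilities based on equal-temperament tones,
    and a synthetic particle-video generator that emulates rigid-bead
    versus compliant-cell responses for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
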