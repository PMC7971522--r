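Package: psrcap
Title: Fibrous-Cap Collagen Quantification from Multi-Angle Linearly
    Polarized Picrosirius Red Images
Version: 0.1.0
Authors@R:
    person("PSR", "Imaging Lab", email = "psrcap@example.org", role = c("aut", "cre"))
Description: Tools for quantifying fibrillar collagen in atherosclerotic
    fibrous caps from stacks of linearly polarized picrosirius-red (PSR)
    microscopy images acquired at multiple slide rotation angles.  The
    pipeline performs blank-slide background subtraction, rotation-prior
    rigid co-registration to the 0-degree reference frame, per-pixel
    maximum-intensity compositing, one-degree ray sector definition of the
    cap region between lumen and necrotic core, and collagen quantification
    by grayscale intensity and by thresholded pixel counting.  A synthetic
    birefringence phantom generator reproduces the crossed-polarizer
    orientation response of collagen fibers so that angular-increment,
    rotation-range and intensity-threshold studies can be run with no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
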