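Package: fragmon
Title: Secondary-Ion Fragment Monitoring for Scanned Carbon-Ion Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for in-vivo treatment monitoring of scanned carbon-ion
    radiotherapy with charged nuclear fragments. Simulates fragment emission
    from a head-phantom model during raster-scanned pencil-beam delivery and
    the response of a two-layer Timepix3-style pixel tracker, reconstructs
    fragmentation vertices from pixel-hit streams (charge-sharing clustering,
    front/back coincidence matching, skew-line midpoint projection onto the
    logged pencil-beam line), and detects internal density changes by
    comparing voxelized fragment distributions with a Poisson significance
    threshold, including the expected-by-chance calibration of that
    threshold, depth profiles along the beam axis, and region-integrated
    fragment-count changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
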