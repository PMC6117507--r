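Package: saltrank
Title: Quantitative Ranking of Salt-Stress Tolerance from Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for ranking plant lines by salt-stress
    tolerance from hyperspectral reflectance cubes. Reads and writes ENVI-style
    rasters, converts radiance to reflectance against a white reference panel,
    removes noisy spectral bands, segments vegetation with NDVI and excess-green
    thresholds, purges mixed edge pixels by morphological erosion, extracts the
    two most spectrally extreme pixels as control and salt endmembers, reduces
    each pixel spectrum to a scalar similarity to the salt endmember by
    projection onto the endmember axis (with constrained quadratic unmixing as a
    cross-check), and computes three ranking statistics: the area under the
    normalized reflectance difference curve on an energy axis, the minimum
    difference of pair assignments (ordinal earth-mover) histogram distance on
    balanced classes, and the Bayesian posterior probability of the salt class.
    Includes a synthetic scene generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    EBImage,
    png
Config/testthat/edition: 3
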