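Package: vertibelt
Title: Cloud-Model Analysis of Mountain Vegetation Vertical Belts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates the internal structure (core zone, upper and lower
    extension zones) of mountain vegetation vertical belts from a digital
    elevation model and a forest-stand inventory map, and quantifies the
    fuzziness and randomness of each belt's elevation distribution with the
    normal cloud model. Provides the backward cloud generator estimating
    expectation (Ex), entropy (En) and hyper-entropy (He) from sampled
    elevations, the forward cloud generator producing membership-weighted
    droplets, elevation-bin area-proportion profiling, mean-proportion
    threshold zonation, regular-grid sampling with aspect stratification,
    and reporting of between-type expectation differences. Includes a
    synthetic single-peak mountain generator with known belt structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
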