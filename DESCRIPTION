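Package: photonbudget
Title: Absolute Photon-Budget Calibration Curves for Microfluidic Optical Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiometric photon-budget modelling of microfluidic fluorescence
    and absorption analysis systems. Given datasheet-style component
    specifications (light source, lens or fiber coupling optics, microchannel
    or thin-film sample, spectral filter, detector, amplifier) and a geometry,
    the package traces photon and electron rates stage by stage through the
    optical train and computes absolute calibration curves (detector output
    voltage versus analyte concentration or molecule count), minimum detection
    limits and dynamic ranges. Includes a seeded Monte-Carlo photon sampler
    for brute-force verification of the algebraic geometric coupling factors,
    a declarative YAML system-configuration format with validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
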