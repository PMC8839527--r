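Package: balticRrs
Title: Semi-Empirical Remote-Sensing Reflectance Modelling for Southern
    Baltic Coastal Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward modelling, calibration and error assessment of a
    five-parameter semi-empirical model of remote-sensing reflectance
    Rrs(lambda) for optically complex (Case 2) coastal waters, at the four
    bands 420, 488, 555 and 620 nm. Component inherent-optical-property
    models link phytoplankton absorption to chlorophyll a and accessory
    pigments, non-algal particle absorption and particulate backscattering
    to suspended matter and its inorganic fraction, and CDOM absorption to
    its value at the 400 nm reference wavelength; reflectance follows from
    the absorption and backscattering budgets through an empirical f/Q
    factor. Includes re-derivation of every model coefficient from station
    tables by log-space least squares, arithmetic and logarithmic error
    statistics (standard error factor), and a seeded synthetic station
    generator emulating southern-Baltic constituent distributions for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
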