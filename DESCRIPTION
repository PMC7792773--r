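Package: vesimech
Title: Membrane Mechanics of Lipid Vesicles from Fluctuation Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates lipid-membrane mechanical parameters from particle-level
    and optical observations of quasi-spherical vesicles. Implements spherical
    harmonics analysis (SPHA) of radial undulations with a Helfrich sphere-model
    fit for the bending rigidity, flicker-noise spectroscopy of giant
    unilamellar vesicle contours (angular autocorrelation, Legendre
    decomposition, statistical and average-based estimators), vesicle
    structural parameters (membrane thickness, area per lipid, radial density
    profiles), and pressure-wave amplitude tracking on planar membranes.
    Includes synthetic-data generators with the matching Helfrich mode
    statistics so every estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
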