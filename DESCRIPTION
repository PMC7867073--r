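Package: nitrauv
Title: Nitrate Quantification from Deep-UV Seawater Absorbance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deep-ultraviolet spectrophotometric retrieval of nitrate
    concentration in seawater. Provides absorbance computation from raw
    intensity spectra, temperature and salinity correction of the
    bromide-dominated sea-salt absorbance via a polynomial low-nutrient
    seawater surface, linear CDOM baseline subtraction, weighted-average
    kernel partial least squares regression with inverse-RMSEP sub-model
    weighting, multiple linear regression and ISUS-style comparators,
    prediction diagnostics, and a Beer-Lambert synthetic seawater spectra
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
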