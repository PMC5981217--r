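Package: fluidspec
Title: Chemometric Identification of Body Fluids from ATR FT-IR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying body-fluid type (peripheral blood, saliva,
    semen, urine, sweat) from attenuated total reflection Fourier-transform
    infrared (ATR FT-IR) spectra. Implements absorbance conversion and
    total-area normalization, NIPALS PLS-DA with a cross-validated
    latent-variable adoption rule, linear discriminant assignment on PLS
    scores, Q-statistic (squared prediction error) outlier rejection with
    Jackson-Mudholkar control limits, and a dichotomous classification tree
    derived from Ward clustering of PLS-DA scores, with two-class PLS-DA
    models at the nodes and one-class Q-tests at the leaves. A synthetic
    spectrum generator with donor-level and replicate-level variability,
    aging drift and an interferent panel makes the whole pipeline testable
    without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    ape,
    optparse
Config/testthat/edition: 3
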