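Package: sludgeRGB
Title: Colorimetric Quantification of Activated-Sludge Biomass from Dish Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates mixed liquor suspended solids (MLSS) in activated-sludge
    cultures from macroscopic photographs of samples in petri dishes. Images are
    reduced to mean red, green and blue intensities over a circular region of
    interest, each channel is calibrated linearly against gravimetric MLSS, and
    a slope-weighted grayscale composite is derived from the three calibration
    slopes. New samples are quantified by inverse prediction, either from the
    linear calibration or from a Beer-Lambert exponential model valid at low
    turbidity. Includes prediction error statistics (RMSE, MAE, MAPE, R^2), a
    synthetic dish-image renderer with channel-specific exponential attenuation
    and sensor noise for end-to-end validation, a bundled reference calibration
    of 23 activated-sludge samples, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    png,
    tiff,
    jpeg,
    jsonlite,
    optparse,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'conditions.R'
    'calibration.R'
    'imaging.R'
    'synthdata.R'
    'quantify.R'
    'cli.R'
    'methods.R'
    'sludgeRGB-package.R'
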