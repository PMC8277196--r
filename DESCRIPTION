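Package: punctakit
Title: Puncta Quantification for Single-Cell Confocal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproducible quantification of fluorescent puncta in confocal
    images of single cells (oocytes): maximum-intensity projection of z-stacks,
    8-bit conversion, white top-hat background suppression, fixed-value
    thresholding, connected-component particle analysis with micron
    calibration, vesicle size-class profiling (phagophore, autophagosome,
    lysosome, amphisome and arbitrary area ladders), peripheral-band
    localization statistics, no-threshold Pearson colocalization, and
    group-comparison conventions (normalization to a reference group,
    mean +/- SEM, unpaired t-tests, one-way ANOVA with Tukey HSD). Includes a
    synthetic-image generator with full ground truth so every stage is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
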