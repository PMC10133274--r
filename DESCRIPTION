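Package: cropsuit
Title: Multi-Crop Land Suitability Mapping from District-Level Yields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Weakly supervised estimation of per-pixel crop suitability
    (predicted attainable yield, bushels/acre) from yield statistics that
    are only published as district-level means. A multi-output multilayer
    perceptron predicts pixel-level yields for several crops at once; an
    averaging head constrains the mean of the pixel predictions over a
    district's cultivated pixels to match the published district yield,
    and a one-hot crop indicator masks the L1 loss so that each training
    example updates only the crop actually observed there. Includes a
    district-held-out k-fold cross-validation protocol with single-crop
    baselines, suitability-map generation with masking and zonal
    summaries, and a synthetic geodata generator with known ground truth
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
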