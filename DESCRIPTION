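Package: endoflow
Title: Microchannel Hemodynamics and Endothelial Junction Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical hemodynamics of rectangular microfluidic channels
    (series-solution velocity field, bottom-wall shear stress, friction-factor
    pressure drop, hydrostatic outlet head) together with a fluorescence-image
    morphometry pipeline for endothelial monolayers: minimum cross-entropy
    thresholding, compartmented nucleus/cell/cytoplasm/membrane-ring
    segmentation, per-cell shape and intensity measures, VE-cadherin junction
    metrics (band coverage, stain width, finger and filopodial protrusion
    length, line-profile colocalization), and a seeded synthetic monolayer
    generator with ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
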