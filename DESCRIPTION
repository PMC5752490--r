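Package: spheroquant
Title: Quantitative Image Analysis of Tumor Spheroids in Microchamber Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-spheroid analysis of bright-field and fluorescence microscopy
    of multicellular tumor spheroids grown in regular microchamber arrays:
    Sobel-edge segmentation of spheroid regions of interest, chamber assignment
    and cross-timepoint tracking, background-subtracted fluorescence metrics
    (mean intensity, positive-area fraction, pixel coefficient of variation,
    two-timepoint intensity ratios, cutoff-based positivity), moment-based
    shape and texture morphometry with cell-count and doubling-time estimates,
    growth-ratio subpopulation classification, collagen-invasion migration
    distances, and a first-order NONOate nitric-oxide release model. Includes
    a synthetic microchamber-array image generator with full ground truth used
    to validate every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
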