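Package: mtlquant
Title: Quantitative Neuropathology and Antemortem MTL Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating quantitative histopathology burden measures to
    antemortem medial temporal lobe (MTL) morphometry. Summarises pathology
    attention heatmaps over contiguous, approximately equal-area segments of
    anatomical sampling regions; pools segment averages into ROI- and
    hippocampus-level burden scores with rule-based inclusion criteria and a
    linear recalibration to the 0-3 ordinal rating scale; validates
    quantitative measures against expert ordinal ratings and staging systems
    with one-sided Mann-Whitney AUC tests; fits ROI-level standardized linear
    models of regional volume and thickness on pathology burden with
    information-criterion comparison of quantitative versus semi-quantitative
    predictors; and performs surface-based cluster-level permutation
    inference with Freedman-Lane residual permutation. A synthetic-data
    module generates heatmaps, ordinal ratings, cohorts and surface datasets
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
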