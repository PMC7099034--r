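Package: cornitrack
Title: Event Staging of Cornification in 3D Time-Lapse Two-Photon Imaging
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the staged events of keratinocyte cornification from
    multi-channel 3D time-lapse fluorescence stacks of stratified epidermal
    models: acidic-vesicle motion arrest via frame-pair Pearson correlation,
    z-expansion and flattening staging from cell-thickness series, nuclear
    DNA-leakage detection from perinuclear ring intensity, mitochondrial
    morphology grouping (punctate versus elongated) with flattening-outcome
    contingency, and condition comparison by the Wilcoxon rank-sum test.
    Includes a synthetic stratified-epithelium image simulator with full
    ground truth so every stage of the pipeline is testable end to end,
    plus rigid xy drift correction, denoising, kymographs, and calibrated
    TIFF stack input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    igraph,
    yaml,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
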