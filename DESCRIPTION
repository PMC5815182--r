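Package: gliamorph
Title: Quantification of Glial Morphology and Activation from Stained Brain Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for quantifying microglia and astrocyte
    number, morphology and activation state from DAB/hematoxylin-stained
    brightfield brain sections: colour deconvolution, tissue and soma
    segmentation, top-hat process extraction, homotopic thinning,
    marker-based proximal/distal arbor decomposition and per-cell
    morphometrics (area, perimeter, form factor, process length, optical
    density). Also computes magnetization transfer ratio (MTR) maps from
    paired MR acquisitions with ROI statistics, relative qPCR fold changes
    (2^-ddCt), and ships a seeded synthetic generator of ground-truthed
    histology fields and MR pairs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
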