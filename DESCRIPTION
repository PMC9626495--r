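Package: miassay
Title: Morphometric Imaging Assay for a Fibroblast Aggregation Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for a morphometric imaging (MI) assay of
    skin-fibroblast aggregation. Implements the image-analysis chain used to
    count cells and measure 48-hour aggregates (despeckle median filter,
    minimum rank filter, rolling-ball background subtraction, iterative
    intermeans binarisation, particle analysis), the field/well/plate quality
    gates on attachment-phase cell density, the Ln(A/N) biomarker averaged
    image-to-well-to-plate, reference-interval percentile cutoffs with exact
    binomial confidence intervals for diagnostic accuracy, and a synthetic
    field and cohort generator with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
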