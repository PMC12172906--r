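Package: PDsubtract
Title: Lesion Volume Change Quantification on Serial PD-Weighted MRI by
    Image Subtraction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated quantification of white-matter lesion volume
    change on serial 2D proton-density-weighted MRI. Two visits are
    registered to a common halfway space, intensity-normalized and
    histogram-matched, and subtracted; the subtraction image is converted
    to Z-scores and thresholded within manual lesion masks to classify
    per-voxel lesion activity as new, enlarging, shrinking or
    disappearing, yielding the total lesion volume change (TLVC).
    Includes a synthetic longitudinal brain-phantom generator with known
    ground truth, and a validation toolkit (transitivity analysis,
    intraclass correlation for absolute agreement, accuracy versus manual
    lesion volume change, atrophy compounding).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Preprocessing, Registration, Segmentation,
    Visualization
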