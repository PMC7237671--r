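Package: lesionqc
Title: Lesion-Wise Evaluation of Binary Segmentations with a Refined
    Sorensen-Dice Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating 3D binary segmentations when the number
    of objects is unknown a priori, as in white matter lesion segmentation
    of multiple sclerosis patients.  Beyond the global Sorensen-Dice index,
    the package classifies every connected component of a segmentation pair
    into a six-class detection taxonomy (correct detection, merge, split,
    split-merge, detection failure, false alarm), reports per-lesion
    Dice-versus-volume tables, volume-threshold sensitivity sweeps, LOESS
    trend curves with confidence bands, cohort heat maps of detection
    classes, and a cross-validated hybrid fusion algorithm that unions
    lesions from the best-performing candidate segmentation in each lesion
    volume stratum.  A synthetic mask and ensemble generator with known
    ground truth supports fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
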