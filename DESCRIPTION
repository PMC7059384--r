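Package: weeddetect
Title: Toolkit for Weed/Crop Detection Pipelines: Plant Masking,
    Synthetic Image Compositing, Anchor Estimation and Detection Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Building blocks for image-based weed and crop detection in
    row-crop fields. Segments plants from soil with the excess-green (ExG)
    vegetation index and Otsu thresholding; generates labelled synthetic
    training images by cut-and-paste compositing of masked plant objects
    under gridded geometric transforms and gamma correction; estimates
    prior anchor-box sizes from training boxes by k-means clustering with
    an IoU distance; represents a two-scale single-stage detection
    architecture as a declarative layer graph with shape inference;
    encodes ground truth onto detection grids and evaluates the
    coordinate/confidence/classification sum-of-squares loss; and scores
    detections against ground truth with IoU matching, precision-recall
    curves, average precision and mAP. A seeded procedural field-image
    generator makes every component testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
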