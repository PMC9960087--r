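Package: blastseg
Title: Segmentation and Classification of Leukemic Blast Cells in
    Stained Blood-Smear Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A classical image-processing pipeline that detects Acute
    Lymphoblastic Leukemia (ALL) blast cells in Romanowsky-stained
    peripheral blood-smear micrographs. Images are denoised with a
    separable two-pass Gaussian blur, converted to HSV color space, and
    masked on the violet/purple hue band characteristic of blast nuclei;
    the mask is cleaned by binary morphological opening with a 5x5
    structuring element, binarized at a fixed threshold, combined with
    the original image by bitwise AND, and traced into contours.
    Image-level cancerous/non-cancerous calls follow from contour
    presence and area, and predictions are scored with confusion-matrix
    metrics (accuracy, precision, recall, specificity, F-measure). A
    deterministic synthetic smear generator with per-image ground truth
    supports testing without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite
Suggests:
    tiff,
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
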