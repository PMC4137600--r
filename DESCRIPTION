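Package: mpsl
Title: Morphological Processing and Successive Localization for 4D Target Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automatic, contour-free segmentation of a gross target volume
    (GTV) across the breathing phases of a 4D CT series using morphological
    processing and successive localization (MPSL): dual-range intensity
    masking, erosion to disconnect the target from surrounding tissue,
    union-find connected-component labeling, a tumor-volume window filter,
    and dilation-based restoration. Includes center-of-geometry motion
    tracking, Dice/sensitivity/PPV overlap metrics, a synthetic 4D chest
    phantom generator with known ground truth, and command-line entry
    points for segmentation, phantom generation, and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
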