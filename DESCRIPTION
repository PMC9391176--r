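Package: ringsift
Title: Concentric-Ring SIFT Matching and Sparse Structure-from-Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature-based matching and sparse 3-D reconstruction for
    two- and three-view image sets. Keypoints are detected as
    difference-of-Gaussian scale-space extrema; local structure is
    summarised by a 64-dimensional descriptor built from Sobel gradient
    fields accumulated over eight concentric rings with eight orientation
    bins each. Candidate correspondences from nearest-neighbour
    distance-ratio matching are filtered by a neighbourhood-voting
    consistency test and a distance-trimmed RANSAC homography stage,
    then fed to normalised eight-point fundamental-matrix estimation,
    essential-matrix pose recovery and linear triangulation. Includes a
    synthetic-fixture generator (textures, warped image pairs, multi-view
    camera rigs) so the whole pipeline is testable without external data,
    and a command-line interface for matching and reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    EBImage,
    withr
Config/testthat/edition: 3
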