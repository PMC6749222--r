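Package: handvein
Title: Contactless Multi-Biometric Verification from Hand Geometry and Dorsal Vein Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An experimental contactless biometric verification pipeline that
    combines hand-contour geometry with dorsal-hand vein minutiae. Provides
    image preprocessing and segmentation primitives (mean/median filtering,
    histogram equalization, global and local mean thresholding, binary
    morphology), hand landmark detection via convex hull and convexity
    defects, a 62-feature hand-geometry vector, vein skeletonization by the
    Zhang-Suen algorithm with crossing-number spur pruning and minutiae
    extraction, four match metrics (Euclidean, RMS-gated Hamming, oriented and
    non-oriented Hausdorff, modified Hausdorff), min-max score normalization
    with arithmetic-mean score-level fusion, and FMR/FNMR/EER evaluation. A
    seeded synthetic hand-image generator with full ground truth supports
    reproducible end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
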