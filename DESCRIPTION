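Package: cephmatch
Title: Automated Structural Superimposition of Serial Cephalometric Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fully automated structural superimposition of serial lateral
    cephalometric radiographs. Keypoint detection is confined to rectangular
    regions of interest enclosed by anatomic landmarks on structures treated
    as stable (anterior cranial base, maxilla, mandible). Oriented corner
    keypoints are described with rotation-steered 256-bit binary descriptors,
    matched by brute-force Hamming distance, filtered with grid-based motion
    statistics, and a robust least-squares rigid transform transfers the
    post-treatment film onto the pre-treatment template. Includes the
    landmark-distance evaluation protocol (pairwise operator differences,
    consensus truth, accuracy versus truth, paired t-tests) and a
    seed-deterministic synthetic cephalogram generator for validation
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
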