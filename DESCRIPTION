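Package: midliner
Title: Markerless Midline Pose Estimation and Locomotion Kinematics for
    Limbless Animals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects limbless animals (larvae, fish, worms) in grayscale
    video as ellipses via a pair-sampling Hough transform on
    background-subtracted difference images, repairs multi-animal
    occlusion and chaining errors with rule-based and score-based
    corrections, reconstructs the body mid-line (pseudo-skeleton) from
    the contour by Voronoi tessellation and shortest-path search, and
    derives locomotion statistics: peristaltic contraction amplitude,
    curvature index, ego-centric thrust/slip/yaw kinematics, saccade and
    thrust-stroke detection, triggered averages, and a permutation test
    on group medians. Includes a synthetic scene generator with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    clue,
    deldir,
    igraph,
    jsonlite,
    polyclip,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    sp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
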