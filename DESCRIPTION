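Package: nemapose
Title: Pose Estimation of C. elegans from Video, Including Coiled Postures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the 2D centerline posture of a single Caenorhabditis
    elegans worm from grayscale video, including self-occluded and coiled
    shapes where classical skeletonization fails. A Gaussian-mixture
    generative model of tangent-angle posture vectors, combined with a patch
    -warping image synthesizer, produces realistic synthetic training images
    from a handful of labeled reference frames; a residual convolutional
    network trained with a head-tail-symmetric angular loss regresses the
    centerline from a single image; post-processing scores predictions by
    normalized-correlation reconstruction error, resolves head-tail
    orientation over time, interpolates and smooths the angle series. A
    behavior module segments roaming and dwelling states with a two-state
    Gaussian hidden Markov model and quantifies body-wave phase dynamics and
    turning statistics in eigenworm coordinates. Procedural fixtures
    generate worm videos with known ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    signal,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
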