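Package: neurocodec
Title: Compression, Detection and Sorting Engines for Multichannel Neural Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Software models of the digital signal-processing engines used in
    implantable neural recording systems: two-stage extracellular spike
    detection with a nonlinear-energy-operator based adaptive threshold
    estimator, lossless and near-lossless intra-channel compression of action
    potentials (second-order DPCM decorrelation followed by Golomb-Rice or
    semi-adaptive arithmetic coding, with run-length framing of inter-spike
    intervals), cross-channel compression of local field potentials by
    temporal and one-tap spatial decorrelation over a minimum-spanning-tree
    channel chain, a bit-accurate 16-tap fixed-point FIR filterbank with a
    saturating 26-bit accumulator, spike-raster packetization, and spike
    sorting with PCA or discriminative-sample features, k-means clustering
    and Euclidean or Mahalanobis assignment.  A synthetic-data generator
    produces multichannel recordings with Poisson spike trains, background
    noise and spatially correlated low-frequency field potentials so that
    every stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    signal,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
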