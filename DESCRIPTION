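Package: ncreann
Title: Linear and Nonlinear Directed EEG Connectivity via Neural-Network nMVAR Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating directed effective
    connectivity from response-inhibition EEG. Band-limited source activity is
    reconstructed with an LCMV beamformer, high-activity voxels are selected by
    their neural activity index and grouped into nodes with DBSCAN, and a
    shallow neural network fits a nonlinear multivariate autoregressive (nMVAR)
    model to the node time courses. The fitted predictor is decomposed into
    linear (LC) and nonlinear (NC) directed connectivity, tested against
    time-shifted surrogate data, and compared across groups and conditions with
    nonparametric statistics. A synthetic-data module generates Simon Go/Nogo
    task designs, behavioral responses, ground-truth-coupled oscillatory
    sources, sensor mixtures and amplitude artifacts, so the whole pipeline is
    testable against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    zoo,
    jsonlite,
    yaml,
    rhdf5,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
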