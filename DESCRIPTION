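Package: ethoseg
Title: Unsupervised Behavioral Segmentation of Depth-Video Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for unsupervised segmentation of rodent
    open-field behavior from top-mounted depth-camera recordings. Includes a
    ground-truth synthetic data generator (switching autoregressive pose
    dynamics rendered as depth video with cohort structure), EM Gaussian
    mouse tracking with ellipse kinematics, aligned-crop PCA pose embedding,
    sticky autoregressive hidden Markov model (AR-HMM) syllable segmentation
    by blocked Gibbs sampling with cross-likelihood validation, and
    group-comparison statistics: syllable usage profiles, bigram transition
    matrices and difference graphs, Jensen-Shannon divergence permutation
    tests, usage-vector embeddings, and kinematic summaries with two-sample
    t statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    Rcpp,
    jsonlite,
    igraph
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    randomForest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
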