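Package: grasprsa
Title: Representational Similarity Analysis of Multimodal Grasping Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how hand grasping movements are represented
    across simultaneously recorded EEG, electromyographic (EMG) and hand
    kinematic signals.  The package implements the full analysis chain:
    synthesis of multimodal grasping sessions with a planted
    condition-similarity structure, preprocessing (band-pass filtering,
    downsampling, epoching, accelerometer-based movement-onset detection,
    trial rejection, Morlet time-frequency decomposition, event-related
    desynchronization maps, Hilbert EMG envelopes, cubic-spline kinematic
    interpolation and principal-component synergies), a searchlight over
    channel and frequency neighborhoods, rank-scaled representational
    dissimilarity matrices (RDMs), categorical grasp models, first-level
    RSA maps with subject-level bootstrap confidence intervals, and a
    second-level RDM of RDMs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
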