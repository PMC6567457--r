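Package: batseg
Title: Acoustically Validated Behavioral-State Segmentation of GPS Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers foraging and commuting behavioral states from
    high-resolution GPS tracks of echolocating bats and validates the
    inference against feeding buzzes recorded by on-board ultrasonic
    microphones.  Implements five segmentation methods (k-means clustering
    of speed and turn angle, four-region binary clustering via a Gaussian
    mixture, first-passage time thresholding, a two-state hidden Markov
    model with gamma step-length and von Mises turn-angle emissions, and
    change-point partitioning of Ornstein-Uhlenbeck correlated-velocity
    models), a feeding-buzz detector operating on call tables or amplitude
    envelopes, balanced-accuracy scoring against buzz-positive locations,
    and a synthetic trip generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    geosphere
Config/testthat/edition: 3
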