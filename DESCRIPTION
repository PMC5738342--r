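Package: PhaseTrack
Title: Segmentation, Tracking and Junction Morphometrics for Endothelial
    Monolayer Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying morphodynamics of confluent endothelial
    monolayers imaged by phase-contrast microscopy. Frames are segmented with
    a binary Markov random field carrying pairwise Potts and robust
    higher-order Pn-Potts clique potentials; elliptical cell candidates are
    proposed as maximal high-probability blobs; candidates are linked into
    trajectories by Metropolis-Hastings sampling of a joint model over
    interacting trajectory collections (constant-velocity motion, smooth
    shape change, non-overlap) followed by a Bayes-risk decision on posterior
    link marginals. Companion morphometrics cover the elongation factor,
    cell perimeter, migration statistics (accumulated and Euclidean
    distance), relative VE-cadherin concentration along junctions, and
    junction-associated plaque counts and sizes. A synthetic monolayer
    simulator with ground truth supports validation end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
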