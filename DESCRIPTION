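Package: dynrsa
Title: Dynamic Representational Similarity Analysis on Simulated Time-Resolved Dissimilarity Structures
Version: 0.1.0
Authors@R: person("dynrsa", "developers", email = "dynrsa@example.org", role = c("aut", "cre"))
Description: Implements dynamic representational similarity analysis (dRSA):
    time-resolved representational dissimilarity matrices (RDMs) are compared
    between a neural data stream and time-varying stimulus-feature models at
    every neural-by-model time point, using principal component regression to
    isolate the unique contribution of each model amid collinear, autocorrelated
    predictors. Includes a seed-reproducible synthetic stimulus generator
    (marker kinematics, rendered grayscale frames, gaze traces), the standard
    stimulus-feature model battery (pixelwise luminance, optical flow magnitude
    and direction, view-dependent and view-invariant body posture and motion,
    eye position), a neural-RDM simulator that implants model RDMs at chosen
    lags with uniform noise, temporal subsampling and realignment, and
    group-level statistics (Fisher Z, one-sided cluster-based permutation
    tests, jackknifed peak latencies, representational spread, BH-FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
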