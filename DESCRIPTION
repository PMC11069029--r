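Package: oscidiff
Title: Oscillatory Correlates of Bimodal Attention and Working Memory:
    Simulation and Group-Difference Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a bimodal (auditory/visual) attention and working
    memory EEG experiment with known ground truth and analyzes it end to
    end: Butterworth high-pass filtering, ICA-based blink removal,
    epoching, artifact rejection, spherical-spline channel interpolation,
    5-cycle Morlet time-frequency decomposition with dB baseline
    normalization against a passive condition, single-trial GLMs of
    oscillatory power with dummy-coded attention/correctness regressors,
    second-level between-group Wilcoxon rank-sum maps corrected by
    cluster-based permutation testing, and the behavioral 2x2x2 mixed
    ANOVA with Greenhouse-Geisser correction and generalized eta squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    car,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
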