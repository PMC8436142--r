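Package: tfsigma
Title: Time-Frequency Sigma Peak Detection and Spindle Comparison for Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects transient sigma-range (10-16 Hz) oscillatory events in
    single-channel sleep EEG from multitaper spectrograms using a two-step
    peak-prominence algorithm followed by unsupervised two-class k-means
    separation of events from background local maxima.  Also provides a
    wavelet-threshold sleep spindle detector with F1 threshold optimization,
    iterative z-score artifact rejection, event-based confusion statistics
    with interval overlap, bin-wise property tests, night-to-night stability
    analysis with permutation testing, EDF and hypnogram input/output, a
    command-line interface, and a synthetic sleep-EEG generator with ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    jsonlite,
    yaml,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
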