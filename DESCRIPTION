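Package: twocap
Title: Behavioral and Neural-Population Analysis of the Two-Way Cued
    Access Protocol
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing cued two-choice alcohol-seeking (2CAP)
    sessions: pose-tracking event extraction (approach detection,
    trial classification, latencies, occupancy, epoch speeds), per-neuron
    adaptive Gaussian-kernel firing-rate estimation, cue-centered and
    side-concatenated population PCA with broken-stick component
    retention, a subspace-permutation left/right distance statistic with
    bootstrap trial pairing, loading-sign population splits with pre/post
    approach side differences, and group-level statistics including a
    latency-distance regression. A synthetic-session generator emulates
    proactive (pre-approach side coding) and reactive (post-approach side
    coding) populations with ground-truth labels so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
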