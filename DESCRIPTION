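Package: signalsim
Title: Simulation of Cell Signaling Network Activity Data for Benchmarking Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates replicate time-series of per-protein percentage activity
    from a user-defined directed signaling network with typed interaction
    strengths. Node activity evolves under a sigmoidal signal-response curve,
    with optional user-specified Gaussian noise on the input-output
    relationship, optional stochastic protein decay in the second half of the
    time series, and external perturbations (drug-like inhibition or
    activation of chosen nodes, optionally released at a given time point).
    Includes readers and writers for SIF/CSV edge tables and trajectory
    tables, demonstration and random network generators, benchmarking
    utilities that score inferred edge lists against the ground-truth network
    (precision, recall/sensitivity, F1) and correlate simulated trajectories
    with reference time courses, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
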