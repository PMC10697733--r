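Package: linseg
Title: Bayesian Partitioning of 1D Data into Piece-Wise Linear Segments
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Partitions a 1D series into contiguous segments, each described
    by a linear combination of user-chosen basis functions, by exact Bayesian
    model comparison.  The marginal likelihood (evidence) is computed for
    every candidate number of segments by summing over all admissible
    boundary configurations with variable elimination, yielding the
    evidence-optimal segment count, posterior boundary locations with
    uncertainties, and per-segment fit statistics.  Handles known per-point
    measurement error and unknown homogeneous error (estimated by
    expectation-maximization and marginalized numerically).  Includes a
    synthetic piecewise-linear benchmark generator and two microbial-growth
    applications: detection of the linear range of optical-density
    calibration curves and automatic identification of exponential (log)
    phase with Monod-equation fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
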