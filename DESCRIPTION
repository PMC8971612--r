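Package: sitstand
Title: Predictive Simulation of Sit-to-Stand Transitions with Muscle
    Strength Deficits and External Assistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A planar musculoskeletal simulator and trajectory-optimization
    framework for the sit-to-stand (STS) transition. Provides a three
    degree-of-freedom linkage (ankle, knee, hip) driven by eight Hill-type
    musculotendon actuators, an event-released kinematic seat constraint,
    nonlinear joint-limit springs, and optional assist-as-needed point
    forces at the torso; an open-loop piecewise-linear excitation controller
    optimized by an active CMA-ES against a ten-term cost function; a
    computed-muscle-control style tracking tool with reserve actuators for
    diagnosing which muscle group's weakness causes STS failure; and
    trajectory/signal analysis utilities (inverse-dynamics torque
    decomposition, phase segmentation, zero-moment-point bookkeeping, EMG
    envelope processing, STS event detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
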