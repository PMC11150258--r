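Package: broadsensor
Title: Adaptive Broad-Learning Soft Sensors for Batch Bioprocesses
Version: 0.1.0
Authors@R: person("Soft Sensor", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Data-driven soft sensors for batch bioprocesses built on the
    broad learning system (BLS) family: the classical BLS with random
    enhancement nodes, a kernel BLS with an exact radial-basis-function Gram
    block, and an approximate-kernel BLS (AKBLS) whose kernel block is built
    from random Fourier features. Models are combined in a stacking ensemble
    with a Gaussian-process meta-learner and wrapped in a moving-window
    adaptive loop for time-varying processes. Includes a self-contained
    fed-batch penicillin fermentation simulator (Birol-style kinetics) that
    generates multi-batch campaigns with varied initial conditions and
    optional measurement noise, plus cross-validated hyperparameter search,
    evaluation metrics, experiment presets and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
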