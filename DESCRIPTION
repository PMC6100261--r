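Package: insilico
Title: In-Silico Kinetic Data Sets via Gauss-Markov Error Superposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction of in-silico data sets for testing parameter
    estimation procedures: simulates ideal concentration time series from a
    semi-batch triglyceride transesterification kinetic model, superposes
    exponentially correlated (Gauss-Markov, AR(1)-type) normally distributed
    measurement error with a relative or constant variance law, estimates the
    six rate constants from one or more experiments by nonlinear least
    squares, and runs Monte-Carlo replicate studies tabulating the mean and
    spread of the recovered parameters at each error level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
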