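Package: stopsignal
Title: Bayesian Ideal-Observer Modeling of Stop-Signal Task Response Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses behavior in the stop-signal task with a
    rational observer model. Within a trial, noisy evidence about the go
    stimulus and the stop signal is filtered by exact Bayes updates, and the
    decision of when to respond is an optimal stopping policy computed by
    backward induction over a discretized belief grid. Across trials, the
    frequency of stop trials is tracked with a dynamic belief model (a
    Bayesian hidden Markov model over the stop-trial rate) and the expected
    stop-signal delay with a scalar Kalman filter. Includes a synthetic
    session generator matching a standard 12-block design, a closed-loop
    observer simulator, and the response-time variability analysis pipeline:
    sequential-effect pattern tables, equal-count binned regressions of go RT
    on model-derived P(stop) and E[SSD], variance partitioning between the
    two predictors, and grid-search recovery of the learning parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    stringr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
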