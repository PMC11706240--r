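Package: satbench
Title: Speed-Accuracy Trade-Off Benchmarking for Human and Dynamic-Network
    Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing timed-response ("beep paradigm")
    categorization experiments and for benchmarking anytime/early-exit
    neural networks against human speed-accuracy trade-off (SAT)
    behaviour.  Provides trial-level quality control (acceptance-window
    observer exclusion, warm-up discard, random-category imputation of
    missing responses), SAT-curve construction and normalization by
    untimed accuracy, a linear timestep-to-reaction-time mapping for
    model observers, cumulative Weibull psychometric fitting, and three
    comparison metrics: curve-fit RMSE averaged over perturbation
    conditions, category-wise Spearman rank correlation, and a
    mean-curvature steepness statistic.  A synthetic-data generator
    emulates both human observers and dynamic-network model observers so
    the full pipeline can be exercised without the original dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
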