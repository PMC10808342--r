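Package: pupilmem
Title: Mixture Modelling of Location Memory with Pupillometry Under Reward Anticipation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous-report location memory experiments
    with concurrent pupillometry under reward-induced arousal. Provides a
    synthetic-data generator emulating a monetary-incentive location-memory
    task (circular targets, adaptive reward-deadline titration, 40-Hz pupil
    traces with blinks), maximum-likelihood fitting of the two-component
    uniform + von Mises mixture of recall errors separating memory success
    from memory precision, density-ratio trial classification, behavioural
    quality-control rules, a pupil preprocessing and event-epoching pipeline
    (blink interpolation, zero-phase Butterworth filtering, baseline
    correction), and paired-design statistics including JZS Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
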