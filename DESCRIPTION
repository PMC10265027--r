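Package: hawkpursuit
Title: Pursuit Guidance-Law Modelling of Hawk Attack Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates planar pursuit trajectories under five candidate
    guidance laws (proportional pursuit, inertial and background-referenced
    proportional navigation, and their mixed PNP forms), fits the guidance
    parameters (navigation gain N, pursuit gain K, sensorimotor delay tau) to
    measured or synthetic flights by RMS-error minimisation, and compares
    models with BCa bootstrap confidence intervals, paired sign tests and
    k-fold cross-validation. Includes a motion-capture preprocessing chain
    (marker labelling, outlier elimination, quintic-spline smoothing with
    analytic derivatives) and a synthetic-data generator emulating a lure
    pursuit arena, so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    boot,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
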