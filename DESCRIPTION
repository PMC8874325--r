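Package: runfatigue
Title: Concurrent Biomechanical and Physiological Fatigue Analysis for
    Endurance Running
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study running-induced acute fatigue from wearable-sensor
    recordings: a synthetic multi-sensor race generator with known ground
    truth (ECG, foot and chest inertial streams, GNSS track, rating-of-fatigue
    log), sensor synchronization and slope-based exclusion, heart-rate
    dynamics extraction (QRS detection, RR artifact correction, time-domain,
    frequency-domain and non-linear HRV/HRC metrics including DFA scaling
    exponents and Poincare descriptors), spring-mass gait mechanics,
    eight-segment race normalization against perceived fatigue, a
    non-parametric statistical battery (Friedman and Wilcoxon signed-rank
    tests with effect sizes, delta-ROF onset analysis, linear mixed-effects
    models by performance group), and linear plus distance-correlation
    association analysis between gait and heart-rate parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    zoo,
    geosphere,
    lme4,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
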