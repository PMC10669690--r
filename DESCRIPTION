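Package: gaitdf
Title: Step-Cycle Normalization and Dissimilarity Factor Analysis of Rodent
    Hindlimb Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hindlimb locomotion kinematics of walking
    rodents from annotated joint landmark trajectories (metatarsus, ankle,
    knee). Provides four-point homographic correction of camera distortion,
    spline-based time normalization of annotated steps to a 100-bin step
    cycle, the dissimilarity factor (DF) statistic computed over cross-animal
    pairs of normalized step curves with Kruskal-Wallis and Dunn post hoc
    group comparison, bin-wise vertical-displacement t-tests with a
    percent-of-step-cycle-changed summary, and a synthetic gait cohort
    generator with ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
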