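Package: pedtape
Title: Evaluation and Recalibration of Length-Based Pediatric Weight
    Estimation Tapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing and recalibrating color-zone, length-based
    pediatric emergency weight estimation tapes (such as the Broselow tape).
    Represents a tape as a validated ordered partition of supine height into
    color zones with associated weight ranges; simulates pediatric cohorts
    with realistic height-weight structure and a tunable tape overestimation
    bias; computes the standard evaluation statistics (directed percent
    differences, within-tolerance accuracy, per-zone sensitivity,
    specificity, Cohen's kappa and chi-square tests, paired t-tests on zone
    weights); and rebuilds a tape for a target population by deriving a
    truncated percent correction factor, re-binning zone heights from
    per-zone confidence intervals, and mapping the new height boundaries to
    weight ranges through a height-weight regression, with validation on an
    independent cohort.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
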