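Package: wormtracer
Title: Automated Multi-Worm Tracking and Behavioral Phenotyping for C. elegans Plate Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies Caenorhabditis elegans locomotor phenotypes from grayscale
    plate videos: per-frame Gaussian smoothing, thresholding and size-gated blob
    detection; centroid-proximity trajectory linking with automated quality gates;
    and per-track behavioral readouts (crawling speed, reversals per minute, body
    bends per minute, fraction of time in a coiled posture). Includes a synthetic
    plate-video simulator with per-frame ground truth for end-to-end validation,
    and the statistical layer used in pharmacological assays on these phenotypes
    (paralysis time courses with log-rank tests, convulsion proportions with
    Fisher's exact test, egg-retention group comparisons, and the percent-rescue
    statistic for drug effects on reversal rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
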