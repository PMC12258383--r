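Package: gcq
Title: Genomic-Control Calibrated Outlier Detection for Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of invalid (pleiotropic) genetic instruments in two-sample
    summary-level Mendelian randomization. Implements GC-Q, a genomic-control
    calibration of per-variant Cochran's Q heterogeneity statistics that corrects
    the overdispersion of first-order weights before Bonferroni-thresholded
    outlier removal, together with the detectors it is benchmarked against
    (first- and second-order-weight Q statistics, the MR-PRESSO global and
    outlier tests, radial MR, and the weighted-median estimator), univariable
    and multivariable inverse-variance weighted estimation, and an
    individual-level two-sample simulation engine with a metric battery
    (sensitivity, specificity, bias, mean squared error, flagged counts).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
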