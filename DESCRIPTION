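Package: fmrmetric
Title: fMR-Metric Analysis of Depth Decoding from ROI Voxel Patterns
Version: 0.1.0
Authors@R:
    person("Pattern", "Analysis Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing multi-voxel pattern decoding of fMRI
    responses with concurrent psychophysical performance. Generates
    one-back history-balanced event-related designs, fits cumulative
    Gaussian psychometric functions with guess and lapse rates, simulates
    region-of-interest voxel time series with graded disparity signals,
    preprocesses runs (high-pass filtering, hemodynamic shift, voxel
    selection by t statistic, trial averaging, z-scoring), decodes near
    versus far depth with a linear support vector machine under
    leave-one-run-out cross-validation, builds permutation null
    distributions for classifier accuracy, and fits fMR-metric functions
    (decoding accuracy versus signal level) for comparison against the
    psychometric function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
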