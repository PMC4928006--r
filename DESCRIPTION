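Package: bstks
Title: Fast Abrupt Change Detection with Binary Coefficient Trees and a
    Modified Kolmogorov-Smirnov Statistic
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects a single abrupt change in a univariate time series by a
    coarse-to-fine binary-tree search over the multilevel Haar wavelet
    decomposition of the signal, routed by a modified two-sample
    Kolmogorov-Smirnov statistic and a variance-fluctuation statistic
    (BSTKS). Ships the classical comparator detectors (exhaustive
    Kolmogorov-Smirnov scan, Welch-t scan, sequential singular spectrum
    analysis), a fully seeded synthetic benchmark generator for Gaussian
    mean-shift and two-regime series, evaluation metrics (hit rate,
    median-location error, accuracy, rank-based AUC, segment e.c.d.f.
    distance), and a command-line entry point for detection, simulation,
    calibration, and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
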