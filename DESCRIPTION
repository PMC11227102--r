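Package: corephi
Title: Bidirectionally Connected Cores and Integrated Information in
    Causal Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for locating the bidirectionally connected core
    ("complex") of a causal brain network estimated by conditional
    multivariate Granger causality, and for quantifying geometric
    integrated information (Phi-G) and mutual information (Phi-M) of
    Gaussian vector-autoregressive systems. Includes session-level time
    series conditioning (trapezoidal tapering, run concatenation,
    decimation, lowpass-interpolation upsampling), group-level statistics
    (participation rates, variogram-matched spatial-autocorrelation
    surrogate permutation tests, Benjamini-Hochberg FDR, intraclass
    correlation, dependent-correlation contrasts), sleep-stage session
    clustering from 30-epoch hypnograms, synthetic cohort generators with
    planted cores, and end-to-end pipeline drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
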