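Package: erpperm
Title: Simulation and Permutation-Based Inference for ERP Priming Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for overt-priming event-related potential (ERP) studies of
    the N250/P325/N400 family: a Latin-square session-design builder with
    filler and lexicality constraints, a synthetic epoched-EEG generator with
    Gaussian component templates, scalp topographies and autocorrelated
    band-limited noise, the standard preprocessing chain (drift correction,
    voltage-step and peak-to-peak artifact rejection, pre-stimulus baseline
    correction, electrode pooling to the 10-20 system, per-condition
    averaging), and resampling inference: pointwise paired t statistics,
    running-t region-of-interest detection with a minimum-duration rule, and
    the sign-flip maximum-t permutation test with empirical critical values,
    including a family-wise error calibration harness on null simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
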