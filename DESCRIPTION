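Package: pctouch
Title: Single-Unit and Population Analyses of Actual and Imagined Touch Encoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing trial-structured spike data recorded during
    actual and imagined tactile stimulation, as used to characterise touch
    encoding in human posterior parietal cortex. Provides a portable on-disk
    session format, per-unit indicator-variable tuning models with false
    discovery rate control, diagonal-covariance linear discriminant decoding
    with leave-one-out cross-validation, cross-validated split-half population
    similarity and permutation contrasts, population response latency
    estimation via first-principal-component piecewise-linear fits, tactile
    receptive-field characterisation (field counts, peak structure, Gaussian
    field size), cross-temporal generalisation and cross-validated Mahalanobis
    (crossnobis) dynamics, and an inhomogeneous-Poisson spike-train generator
    with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
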