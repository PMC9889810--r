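Package: gridtrack
Title: Hexadirectional Grid-Code Analysis for Observed Navigation in a
    Circular Arena
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect grid-like (n-fold directionally periodic)
    modulation of regional fMRI time series while an agent traverses a
    circular virtual arena. Provides constrained trajectory generation
    with balanced direction sampling, behavioural scoring against a
    permutation-based random-agent chance level, quadrature parametric
    GLM estimation of grid orientation with cross-validated magnitude
    testing at control symmetries, representational-stability metrics
    based on circular statistics, saccade-based eye-movement controls,
    and a synthetic-data module that simulates directionally modulated
    BOLD responses, noisy path re-tracing, and gaze traces with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
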