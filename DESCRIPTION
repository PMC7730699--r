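Package: pollenfuse
Title: Multisensor Data Fusion for Bee Pollen Sensometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for characterizing bee pollen by botanical
    origin from fused instrument blocks. Implements CIELAB colour
    characterization (chroma, hue angle, colour differences with
    perceptibility categories), block-specific signal pretreatment
    (Savitzky-Golay smoothing, multiplicative scatter correction, spectral
    truncation, additive session-drift correction for electronic-tongue
    arrays, Fisher-ratio sensor selection for electronic-nose arrays),
    PCA and cross-validated LDA classification, NIPALS partial least
    squares regression with grouped cross-validation and prediction-based
    outlier removal, low-level block fusion, quantitative descriptive
    sensory analysis (two-way ANOVA with Tukey HSD letters, summary-based
    one-way ANOVA), and a seeded synthetic study generator emulating the
    full five-class design so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    mixOmics
Config/testthat/edition: 3
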