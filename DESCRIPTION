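Package: punctascreen
Title: High-Content RNAi Screen Analysis for Image-Based Autophagy Phenotypes
Version: 0.1.0
Authors@R:
    person("Plate", "Works", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multiplex image-based RNAi screens that
    monitor punctate (spot) phenotypes such as autophagosome markers. Covers
    synthetic data generation (plate layouts, effect models, rendered well
    images, qPCR Ct tables, AP-MS spectral counts, expression ratios), nucleus
    and cytoplasm segmentation with per-cell spot detection and integrated
    spot signal, plate normalization to non-targeting controls with z'-factor,
    z-score and B-score quality statistics, standard-deviation hit calling
    with cytotoxicity filtering and siRNA deconvolution validation, relative
    qPCR quantification against a reference-gene geometric mean, ChIP-qPCR
    percent-input, CompPASS-style weighted-normalized D-score interaction
    scoring, and fold-change gating of expression ratio tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
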