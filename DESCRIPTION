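Package: mesocortex
Title: Cell-Type-Specific Analysis of Widefield Cortical Calcium Imaging
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An analysis pipeline for dual-wavelength widefield calcium
    imaging of dorsal cortex during decision-making. Provides hemodynamic
    correction from interleaved blue/violet illumination, SVD compression,
    zero-phase high-pass filtering, four-epoch trial alignment, semi- and
    region-localized nonnegative matrix factorization with variance-criterion
    rank selection, UMAP-based component embedding with leave-one-animal-out
    type classification, a trial-based ridge encoding model with per-column
    marginal-likelihood penalty selection, a per-timepoint L1 logistic choice
    decoder, and single-neuron ROC/AUC choice-selectivity statistics with
    permutation nulls. Includes a synthetic-session generator with ground
    truth so every stage is testable without real recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    glmnet,
    uwot,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vegan,
    cluster,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
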