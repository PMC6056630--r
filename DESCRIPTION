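Package: somportraits
Title: Self-Organizing Map Portrayal of Blood Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Modular analysis of bulk blood transcriptomes by self-organizing
    map (SOM) "portrayal": quantile normalization and gene-wise centralization,
    batch-SOM training of metagene landscapes, per-sample expression portraits,
    variance-map segmentation of co-expression spot modules, Fisher spot
    enrichment and sample-wise gene set Z (GSZ) scoring, correlation-based
    class discovery with silhouette refinement and bootstrap stability, and a
    pixel-resolution prognostic map linking metagene over-expression to 28-day
    survival. Includes a synthetic cohort generator that plants latent
    severity, interferon-response and blood-disturbance axes with ground truth
    for recovery testing, plus an end-to-end pipeline with tabular and image
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    igraph,
    mclust,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
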