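Package: eedomics
Title: Integrative Histology, Transcriptome and Metabolic Modeling Pipeline
    for Environmental Enteric Dysfunction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale re-implementation of an integrative
    analysis of environmental enteric dysfunction (EED): whole-slide-image
    patch extraction with tissue filtering and stain normalization, a compact
    convolutional patch classifier with pre-final-layer feature extraction and
    class-activation saliency, probability-weighted patient-level feature
    aggregation, genome-wide feature-gene and feature-biomarker correlation
    screens with Benjamini-Hochberg control, transcript-contextualized
    metabolic network modeling (FBA, parsimonious contextualization, flux
    sampling), random-forest extraction of discriminative reactions, and
    permutation-based lipid set enrichment analysis. A synthetic-data module
    with planted ground truth drives every stage so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    boot,
    png,
    jsonlite,
    yaml,
    xml2,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
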