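Package: gammscope
Title: Quantitation and Pro-Inflammatory Scoring of Glioblastoma-Associated
    Microglia and Macrophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for glioblastoma-associated
    microglia/macrophage (GAMM) content and activation state. Provides
    automated per-cell quantitation of multi-channel immunofluorescence
    images (nuclear counterstain, Iba1, one inflammatory marker) with
    positivity thresholds calibrated against no-primary-antibody controls,
    site-level quality filters, per-tumor aggregation of marker frequencies,
    a composite min-max-scaled pro-inflammatory activation score with
    median-split survival comparison, and hypergeometric enrichment of
    hierarchically clustered single-cell expression profiles against curated
    microglia/macrophage gene lists. A synthetic-data generator with known
    ground truth (images, cohort tables, expression matrices) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    Matrix,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
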