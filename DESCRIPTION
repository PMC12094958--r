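Package: cmfelseg
Title: Coarse-to-Fine Cascaded and Ensemble-Fused Multi-Structure
    Segmentation for Craniomaxillofacial CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of a coarse-to-fine cascaded,
    ensemble-fused multi-structure segmentation pipeline for
    craniomaxillofacial (CMF) CT volumes. Provides a synthetic labeled
    phantom generator (soft-tissue envelope, skull shell, mandible arch,
    cervical vertebrae, hyoid, pharyngeal airway, inferior alveolar nerve
    canals and up to 32 FDI-numbered teeth), three scaled volumetric
    encoder-decoder segmenter families behind one prediction contract, a
    two-stage coarse-to-fine cascade with dentition ROI extraction and a
    dual-head (33-class / 5-class parity) fine stage with adjacent-tooth
    identity correction, AdaBoost-weighted soft-voting ensemble fusion,
    and an evaluation surface with per-class Dice/IoU, symmetric surface
    distances, group comparison tests and a four-grade quality rubric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
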