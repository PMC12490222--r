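Package: blastscreen
Title: Image-Based Ex Vivo Drug Sensitivity Profiling for Pediatric AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for image-based ex vivo drug sensitivity
    profiling of pediatric acute myeloid leukemia samples: well and cell
    quality control, semi-supervised single-cell viability labeling
    (dimensionality reduction, density clustering, per-cluster Gaussian
    mixtures, confidence and nearest-neighbour consensus filters),
    blast-specific relative-blast-fraction (RBF) dose-response scoring with
    outlier filtering and RBF-AUC / Blast-AUC summaries, drug and drug-class
    correlation analysis with false-discovery control, projection of
    chromatin-accessibility profiles onto a labeled healthy hematopoietic
    reference with a Mono-HSC propensity score, and cross-validated
    prediction of clinical response from sensitivity profiles. Includes a
    synthetic cohort generator with planted effects for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    mclust,
    e1071,
    ranger,
    FNN,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    uwot,
    withr,
    yaml
Config/testthat/edition: 3
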