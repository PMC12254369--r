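Package: cmaflux
Title: Chaperone-Mediated Autophagy Scoring and Lysosomal Flux Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipelines for studying chaperone-mediated autophagy
    (CMA) from omics data: a weighted, directional transcriptional CMA score
    computed over a configurable gene network (LAMP2A double-weighted);
    qPCR-derived relative expression (2^-deltaCt); a lysosomal-flux proteomics
    classifier (log2 transform, per-sample normalisation, downshifted-normal
    imputation of missing values, Welch differential abundance, and set logic
    calling lysosomally degraded proteins, CMA substrates via LAMP2A
    knockdown, and drug-sensitive substrates); cohort statistics
    (expression-ratio versus score regression, mutation-status
    stratification, fold-change filtering, and z-score hit calling for
    high-content screens); and seeded synthetic-data generators with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
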