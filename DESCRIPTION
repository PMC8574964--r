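Package: TMEnet
Title: Contamination-Adjusted Expression and Signalling Networks of the
    Tumour Microenvironment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing sorted-cell bulk RNA-Seq profiles of the
    ovarian-cancer omental tumour microenvironment. Implements marker-based
    estimation of cross-contamination between sorted cell populations,
    exclusion of over-contaminated samples, linear unmixing of TPM profiles,
    cell-type-selectivity classification of cytokine and growth-factor genes,
    ligand-to-receptor target scoring, patient-matched compartment
    differential expression, secretome/transcriptome concordance, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
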