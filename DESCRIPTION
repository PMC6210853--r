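Package: HCCrisk
Title: Molecular Risk Scoring and Subclassification of Hepatocellular Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls six binary molecular features per hepatocellular carcinoma
    (CTNNB1, TP53 and TERT-promoter mutation, tumor-suppressor-gene promoter
    hypermethylation, global hypomethylation of repetitive elements, and high
    fractional allelic loss), subclassifies tumors by correspondence analysis of
    the binary events followed by hierarchical clustering, computes a four-factor
    (and three-factor copy-number surrogate) molecular risk score with an
    aggressive/mild pattern call, and provides the association and
    recurrence-free-survival statistics used to evaluate the score. Includes a
    synthetic cohort generator calibrated to the published subclass prevalences
    so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    MASS,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
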