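Package: epnsig
Title: Molecular Group Classification of Paediatric Ependymoma from
    Targeted Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for molecular classification of paediatric ependymoma
    from targeted gene-expression signatures. Implements discovery of
    group-specific marker genes from labelled expression matrices via a
    resampled Student t-test scheme, technical (positive-control) and
    biological (housekeeping) normalization of NanoString nCounter RCC
    lane files, reference-anchored hierarchical-clustering assignment of
    tumours to the RELA fusion-positive, YAP1 fusion-positive, PFA and
    PFB molecular groups (with PFA1/PFA2 and NELL2/LAMA2 strata), and
    the downstream fusion-concordance and survival statistics. Includes
    synthetic-cohort generators so the full pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
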