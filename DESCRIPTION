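Package: cupclf
Title: Tissue-of-Origin Classification of Carcinoma of Unknown Primary
    from DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for predicting the organ of origin of carcinomas of
    unknown primary (CUP) from Illumina methylation-array beta values.
    Provides probe and sample quality-control filters, beta/M-value
    transforms, empirical-Bayes (ComBat-style) batch correction,
    restriction to organ-specific methylation quantitative trait locus
    (mQTL) probe sets for six organ classes (breast, lung,
    ovarian/gynecologic, colon, kidney, testis), variance-based feature
    selection, a fully connected neural-network classifier with dropout,
    stratified cross-validation with multiclass metrics, and a synthetic
    methylation-cohort simulator used to validate every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
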