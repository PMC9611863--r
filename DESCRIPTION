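Package: tissuespec
Title: Tissue-Specificity Screening and Validation for Expression Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-database screening for tissue-specific gene expression
    from genes-by-tissues TPM matrices, cross-database consensus filtering,
    qPCR relative quantification against multiple reference genes,
    tumor-versus-normal cohort statistics, and co-expression clustering on a
    sign-blind Spearman correlation distance. Includes synthetic-data
    generators with planted ground truth so every stage is testable offline,
    plus readers and writers for GCT 1.2 and TSV expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
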