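Package: gbanet
Title: Guilt-by-Association Gene Function Prediction from Co-Expression
    and Literature Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable implementation of a cross-evidence
    "guilt by association" procedure for linking genes to phenotypes.
    Expression panels are quantile normalized and each gene's K nearest
    co-expression neighbors (Pearson r) are extracted; a thesaurus-driven
    literature co-occurrence network is built from a corpus of abstracts;
    commonalities shared by a query gene set are scored by shared
    relations, observed/expected ratio under a degree-proportional null,
    and their product. Companion stages provide strain-panel Pearson
    gene-phenotype screening, hypergeometric overrepresentation analysis
    with Benjamini-Hochberg adjustment, and robust modified Z-score
    expression profiling. A synthetic-data module plants co-expression
    modules, literature concepts, trait effects and gene sets with known
    truth so every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
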