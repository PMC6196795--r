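Package: plsmirnet
Title: Partial Least Squares Inference of miRNA-mRNA Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Integrative analysis of paired miRNA and mRNA expression
    profiles from stress/control designs. Implements quantile
    normalization and moderated-t differential expression, sequence
    complementarity scoring of miRNA target sites with an expectation
    penalty, partial least squares (PLS) regression association scores
    between every differentially expressed miRNA and mRNA, resampling
    based significance with Benjamini-Hochberg false discovery rate
    control, construction of the bipartite miRNA-mRNA regulatory network
    with degree-distribution fits and coregulatory module detection, and
    ROC-based expression validation. A synthetic-data generator with
    planted regulations supports end-to-end benchmarking of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    igraph,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
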