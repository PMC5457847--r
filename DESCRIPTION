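Package: mirpathnet
Title: miRNA-mRNA-Pathway Risk Network Inference from Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers disease risk pathways, risk genes and regulatory miRNAs
    from case/control expression profiles. Combines per-study differential
    expression (Welch or empirical-Bayes moderated t) by Fisher's method,
    runs a phenotype-permutation gene set enrichment analysis with
    leading-edge (core gene) extraction, selects consensus risk pathways
    across datasets, scores miRNA-pathway associations by an upper-tail
    hypergeometric test with Benjamini-Hochberg adjustment, assembles a
    tripartite miRNA-gene-pathway network with a protein-protein interaction
    overlay and node topology metrics, ranks single-feature biomarkers by
    cross-validated ROC AUC, and matches differentially expressed miRNAs
    across species by mature-name normalization. Ships a synthetic-data
    generator with planted ground truth so the whole pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    limma,
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
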