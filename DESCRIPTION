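Package: tcrpair
Title: Clonality Analysis of Paired-Tissue Single-Cell TCR Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing paired blood/tissue single-cell T-cell
    receptor (scTCR-seq) repertoires: paired alpha/beta clonotype calling
    from CDR3 amino-acid sequences, per-patient per-tissue abundance and
    clonal expansion classification (Single, Small, Medium, Large,
    Hyperexpanded), cross-tissue clonotype enrichment scoring, cluster-level
    quantification and clonotype overlap, exact CDR3 annotation matching
    against VDJdb-style tables, bulk TCR-beta clone-table re-scoring,
    cell-level QC filtering, CLR-based ADT gating of CD4/CD8 single-positive
    T cells, and Wilcoxon rank-sum differential expression between
    clonality-defined cell groups. Includes a seeded synthetic repertoire
    generator with ground truth so every pipeline stage can be exercised and
    validated without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
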