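Package: clonoscope
Title: Single-Cell TCR Repertoire Clonality, Specificity Grouping and
    Epitope Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paired alpha/beta T cell receptor (TCR) repertoire
    analysis from single-cell V(D)J contig tables: clonotype calling pooled
    across samples, the D50 repertoire diversity statistic, downsampling-based
    clonal-expansion comparisons between condition groups, per-cluster Fisher
    enrichment of clonally expanded cells, CDR3 similarity clustering into
    antigen-specificity groups, TCR-sharing lineage evidence across
    transcriptomic clusters, and linkage of TCR specificity groups to HLA
    alleles and candidate peptide epitopes through sample-set sharing. A
    synthetic repertoire generator with full ground truth makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
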