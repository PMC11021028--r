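Package: mppeqtl
Title: Tissue- and Treatment-Specific eQTL Mapping in Multiparental
    Recombinant Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for expression QTL (eQTL) mapping in
    multiparental recombinant inbred panels such as the Drosophila
    Synthetic Population Resource (DSPR). Provides factorial differential
    expression of RNA-seq counts (TMM normalization, gene-wise linear
    models, empirical-Bayes moderated statistics, Benjamini-Hochberg FDR),
    preparation of expression traits including signed treatment-response
    traits (log2 and quantile normalization, principal-component removal
    of technical structure, rank-based inverse-normal transformation),
    Haley-Knott regression genome scans on 8-founder additive haplotype
    probabilities with gene-specific permutation thresholds, peak calling
    with LOD-drop support intervals, cis/trans classification, founder
    effect estimation, cross-dataset eQTL sharing, and hypergeometric
    gene-set enrichment. A synthetic data generator produces DSPR-like
    founder mosaics and negative-binomial counts with planted eQTL so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
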