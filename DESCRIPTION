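Package: kzfpscape
Title: Comparative Analysis of KRAB Zinc-Finger Protein Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the evolution of KRAB zinc-finger protein (KZFP)
    gene clusters from genome assemblies: detection of C2H2 zinc fingers and
    extraction of DNA-contacting fingerprint residues, rule-based
    classification of KZFP transcripts as coding, pseudogene or other,
    definition of cluster loci from flanking anchor genes, comparison of
    fingerprint-array repertoires between assemblies, inference of duplicated
    gene blocks from 3' exon similarity, transposable-element enrichment and
    divergence-landscape statistics with permutation nulls, ChIP-seq peak
    filtering and peak-repeat association, and curation of contig-level
    assemblies from PAF alignments. A seeded simulator generates toy cluster
    genomes with full ground truth so the whole pipeline can be validated
    against planted features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
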