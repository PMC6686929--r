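Package: lncphylo
Title: Phylogenetic Signal in Molecular Traits of Plant lncRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of molecular traits of long non-coding RNAs
    (lncRNAs) across species. Extracts spliced transcript length, exon count,
    GC content and maximal open reading frame length from genome FASTA and
    GFF3/GTF annotation, classifies assembled transcripts against a reference
    annotation by intron-chain matching to quantify novel and intergenic
    lncRNAs, and estimates phylogenetic signal in per-species class mean
    traits with Moran's I (permutation test and 100-point local correlogram
    with bootstrap confidence intervals), Blomberg's K and maximum-likelihood
    Pagel's lambda, followed by Brownian-motion versus Ornstein-Uhlenbeck
    model comparison. Includes seeded simulators for trees, tip traits and
    whole synthetic study fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    jsonlite
Config/testthat/edition: 3
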