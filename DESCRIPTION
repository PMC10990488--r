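Package: retromark
Title: Transposon Expression as a Readout of Intron Retention and
    Transcriptional Readthrough
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of transposable-element expression, intron
    retention and transcriptional readthrough in RNA-seq count data.
    Classifies transposon loci by genomic context (genic, intronic,
    gene-proximal, intergenic), derives downstream-of-gene readthrough and
    upstream read-in regions in 10-kb bins, computes nearest-gene-normalized
    per-sample expression scores and log2 readthrough-to-gene ratios, runs
    simplified covariate-adjusted differential expression, correlation and
    partial-correlation analyses, and annotates LINE-1 loci for ORF1p/ORF2p
    coding potential via global protein alignment with a permutation null.
    Ships a seeded synthetic-data generator (annotation, element sequences
    and negative-binomial counts with injected aging or senescence effects)
    so that every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
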