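Package: repeatlock
Title: Repeat-Stabilizing Knock-In Design for Coding Mononucleotide Repeats
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design toolkit for correcting frameshift mutations in coding
    mononucleotide repeats while stabilizing the repaired tract. Long
    homopolymer runs inside a CDS are hypermutable under mismatch-repair
    deficiency; repeatlock enumerates synonymous frame-restoring insertions
    that split such a run into two shorter runs, ranks them, and turns the
    top design into an rAAV Gateway targeting construct with attB-tailed
    homology-arm primers and PCR screening assays with expected amplicon
    sizes. It also implements the statistics used to validate edited
    clones: delta-delta-Ct relative quantification against multiple
    reference genes, cross-clone fold-change intersection, hypergeometric
    gene-set overlap with Benjamini-Hochberg adjustment over a fixed
    family, and ChIP peak genic/TSS enrichment summaries. Deterministic
    synthetic-data generators make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    fgsea,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
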