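Package: utrx
Title: Detection of Transcription Read-Through and 3'UTR Extensions from
    Strand-Specific RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect defective transcription termination from
    strand-specific RNA-seq data. Intergenic regions downstream of annotated
    transcript 3' ends are tiled into fixed-width bins, bin counts are
    normalized with median-of-ratios size factors, and 3'UTR extensions are
    assembled contiguously from each termination site until normalized
    coverage drops below a threshold, then filtered by length. Extensions are
    tested for differential read-through between genotypes via the
    extension-to-gene-body ratio with Benjamini-Hochberg correction. The
    package also profiles nucleotide composition around cleavage sites,
    locates near-upstream polyadenylation elements (NUE) and compares their
    base frequencies between gene sets with a chi-square test, and computes
    qPCR long-to-short transcript ratios from cycle-threshold tables. A
    seeded synthetic-data generator produces toy genomes, negative-binomial
    coverage with genotype-dependent read-through, and cleavage-site
    sequences with planted NUE hexamers, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
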