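Package: asmqc
Title: Quality Control for Long-Read Fungal Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-set and assembly evaluation for Oxford Nanopore-only fungal
    genome assemblies. Computes Nx statistics, applies length/quality read
    filtering and seeded coverage-targeted subsampling, derives average
    mapping completeness from terminal soft/hard clips in alignments,
    detects telomere-repeat arrays (TTAGGG/CCCTAA) at contig ends by exact
    sliding-window motif search, classifies contigs as true, artifact or
    high-copy from their depth relative to the coverage plateau of the
    nuclear contigs, and profiles homopolymeric versus random indel errors
    by global pairwise alignment of trusted gene sequences against their
    assembled copies. Includes seeded simulators that generate reads,
    assemblies, alignments and mutated genes with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    BiocGenerics,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
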