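Package: viromics
Title: Virome Assembly Benchmarking, Duplicate-Contig Networks and Viral Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking metagenome assemblies of environmental
    viromes and annotating the resulting contigs. Includes a seeded simulator
    for virome sequencing experiments (skewed abundance profiles, genome
    fragmentation, coverage spike-ins, paired-end reads with an Illumina-like
    substitution error model, and mock assemblies with planted errors); a
    size-stratified assembly evaluator (misassembly classification, N50,
    genome recovery); network-based detection of near-identical contig
    clusters produced by excessive read coverage, with cluster-specific read
    partitioning and containment deduplication; score-based taxonomic kingdom
    assignment of predicted proteins with a viral keyword dictionary and
    MEGAN-style lowest-common-ancestor placement; and annotation of small
    circular Rep-encoding ssDNA virus genomes (circular ORF prediction,
    rolling-circle replication origin stem-loops, Rep motif scanning).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
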