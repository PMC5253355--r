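# viromics

Tools for benchmarking metagenome assemblies of environmental viromes and
annotating the resulting contigs.

Virome libraries bring two assembly pathologies that whole-dataset averages
hide. Genomes are often fragmentally represented, and assemblers differ in
how often they join unrelated fragments into chimeras at particular contig
sizes. Worse, small circular ssDNA genomes (circovirus relatives) are
preferentially amplified during whole-genome amplification and reach
coverages thousands of times the library average, which drives some
assemblers to emit hundreds of near-identical copies and sub-sequences of a
single replicon. This package implements the full informatics for studying
and handling both effects:

* **Simulation** — seeded generation of skewed (lognormal) abundance
  profiles, 2 kb genome fragment libraries (optionally discarding every
  second fragment), coverage spike-ins for circular genomes, paired-end
  reads with a normal insert model (450 nt, 10% sd) and a position-ramped
  substitution error model (1% at 300 nt, 0.9% at 80 nt), and mock
  assemblies with planted, labelled errors.
* **Assembly evaluation** — k-mer anchor alignment of scaffolds to truth
  genomes, misassembly classification (chimera / non-collinear /
  low-coverage / over-length), per-size-bin statistics, N50
  (largest `L` such that sequences `>= L` sum to at least half the total
  length), and genome *hit* / *recovered* accounting, where recovery
  demands a single correct scaffold covering >= 90% of the genome. In
  fragment mode, a 5% over-length allowance marks every scaffold
  `>= 1.05 x` fragment length (2.1 kb for 2 kb fragments) as misassembled.
* **Duplicate-contig networks** — all-vs-all near-identity comparison
  (>= 98% identity over >= 90% of the shorter contig), clustering by
  connected components, strict `coverage > 5000` flagging, per-cluster
  read partitioning for targeted reassembly, and containment
  deduplication of clusters down to their distinct sequences.
* **Kingdom assignment** — the score-based decision rules over hits from a
  viral screening database (viral iff bit > 50), NCBI-nr and RefSeq-P:
  class Viruses when (a) the screening hit scores strictly highest,
  (d) a protein domain is itself viral, (b) the best cellular-database hit
  is taxonomically viral at e-value < 1e-4 and bit >= 45, or (c) its title
  carries a viral keyword at the same thresholds; putative-Viruses for
  sub-threshold viral evidence; otherwise the cellular kingdom or
  unclassified. Plus MEGAN-style LCA placement (min score 45, max e-value
  1e-4, top percent 10, min support 1, LCA percent 100) and an rRNA
  contamination screen (distinct reads with hits at bit >= 80).
* **Circovirus-like annotation** — six-frame ORF prediction that follows
  genes across the origin of circular contigs, detection of rolling-circle
  replication origins (nonanucleotide-family motif in the loop of an
  inverted-repeat stem), and Rep motif I/II/III scanning
  (`FTINN/HLQG/YCKKD`, degenerate `H.Q`/`Y.KD`/`Y.KE`, `FLTF/HLH/YCMKD`).

See the vignette (`vignettes/virome-informatics.Rmd`) for the models,
parameter semantics and design decisions.

## Worked example

Simulate a five-genome virome with one excessively covered circular
genome, build a mock assembly with planted errors, evaluate it, and detect
the planted duplicate cluster:

```r
library(viromics)

g <- random_genomes(5, c(8000, 12000, 20000, 3000, 2000), seed = 42)
g$circular[5] <- TRUE
profile <- sample_abundance_profile(5, sigma = 1.5, seed = 42, ids = g$id)
spiked  <- make_spiked_profile(profile, "g5", spike_fold = 1000)
round(spiked, 4)
#>     g1     g2     g3     g4     g5
#> 0.0042 0.0002 0.0009 0.0014 0.9932

reads <- simulate_read_pairs(g, spiked,
                             sim_config(5000, read_length = 300, seed = 42))
mean(reads$end - reads$start)   # observed mean insert: 449.5 nt

plan <- mock_assembly_plan(
  faithful = data.frame(genome = g$id, start = NA, end = NA),
  chimera  = data.frame(genome_a = "g1", start_a = 0, end_a = 1500,
                        genome_b = "g2", start_b = 5000, end_b = 6500),
  duplicate_cluster = data.frame(genome = "g5", n = 12,
                                 max_truncation = 0.1,
                                 mutation_rate = 0.005),
  seed = 42)
mock <- generate_mock_assembly(g, plan)

evaluate_assembly(mock$scaffolds, g)
#> Assembly evaluation
#>   Number of scaffolds (% misassembled): 18 (6)
#>     500-999 nt       0 (na)
#>     1-1.999 kb       12 (0)
#>     2-4.999 kb       3 (33)
#>     5-9.999 kb       1 (0)
#>     10-19.999 kb     1 (0)
#>     20-49.999 kb     1 (0)
#>     ...
#>   Max scaffold length: 20000
#>   N50: 8000
#>   Scaffolds correctly mapped to genomes: 17 (94%)
#>   Number of misassembled scaffolds: 1
#>   Total correctly assembled length (Mb): 0.1
#>   Genomes hit: 5
#>   Genomes recovered: 5

e  <- pairwise_near_identity(mock$scaffolds)
cl <- connected_components(e, mock$scaffolds$id,
                           setNames(nchar(mock$scaffolds$sequence),
                                    mock$scaffolds$id))
length(cl[[1]]$members)   # 13
cl[[1]]$representative    # "faithful_5"
```

The single misassembled scaffold is the planted chimera (reason
`multi-genome`). The duplicate network finds one cluster of 13 members:
the 12 planted near-identical copies *plus* the faithful copy of `g5`
itself, which is exactly how excess-coverage duplicates present in a real
assembly; `deduplicate_cluster()` reduces such a cluster to its distinct
sequences, and `partition_reads()` extracts the cluster's reads for a
separate reassembly.

A thin command-line wrapper over the same functions ships in
`inst/exec/virotool.R` (`sim`, `eval`, `dedup`, `circo` subcommands); the
exported functions are the primary interface.

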