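---
title: "Virome assembly benchmarking and annotation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virome assembly benchmarking and annotation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromics)
```

## The problem

Environmental viromes — shotgun libraries sequenced from purified
virus-like particles — pose two assembly pathologies that averaged
statistics hide. First, genome populations are fragmentally represented:
many genomes yield only short scattered contigs, and assemblers differ
sharply in how often they join unrelated pieces into chimeras at
particular contig sizes. Second, small circular ssDNA genomes (circovirus
relatives) are preferentially amplified by rolling-circle whole-genome
amplification and arrive at coverages orders of magnitude above the rest
of the library; several assemblers respond by emitting hundreds of
near-identical copies and sub-sequences of one underlying replicon.

This package provides the informatics for studying and handling both
pathologies end to end: a seeded simulator that reproduces the relevant
data features, a size-stratified assembly evaluator with explicit
misassembly classification, a network method that detects and collapses
duplicate-contig clusters and partitions reads for targeted reassembly,
a rule-based taxonomic kingdom classifier for predicted proteins with
MEGAN-style LCA placement, and annotation tools for circovirus-like
genomes (circular ORFs, rolling-circle origins, Rep motifs).

## The simulator

`sample_abundance_profile()` draws per-genome relative abundances from a
lognormal (log-sd `sigma`, default 1.5), the standard stand-in for the
strongly skewed species-abundance curves of environmental viromes when a
real composition table is unavailable. Weights are genome *copy numbers*:
`simulate_read_pairs()` samples a template per read pair with probability
proportional to `weight * genome length`, the per-copy convention used by
established read simulators. Three canonical experiment designs are
covered:

* a plain multi-genome virome (profile + genomes);
* a fragmentation experiment: `fragment_genomes()` cuts genomes into
  consecutive windows of exactly 2 kb starting at position 1, discards a
  trailing short window, and optionally discards every second window so
  that retained fragments never abut. The kept set is the even-indexed
  windows; the choice of which alternate half to keep is arbitrary and is
  fixed for reproducibility.
* a coverage spike-in: `make_spiked_profile()` gives selected (small,
  circular) genomes `spike_fold` times the median base weight before
  renormalisation. The default `spike_fold = 1000` makes the spiked
  genomes absorb most of the library, which is the regime of interest —
  "excessively covered" rather than merely abundant; the factor is
  configurable and nothing downstream depends on its exact value.

Reads are paired-end with inserts drawn from a normal distribution (mean
450 nt, sd 10% of the mean by default), rounded, clamped to
`[read length, template length]`; the start position is uniform, with
wrap-around permitted on circular templates, and read 2 is the reverse
complement of the far end of the insert. Substitution errors follow a
position-dependent ramp rising linearly from 0.5x to 1.5x the target rate
along the read, so that the mean per-base rate equals the configured
value (1% for 300 nt reads, 0.9% for 80 nt reads by default) while
retaining the qualitative 3'-degradation of real Illumina data. Base
qualities encode the per-base error probability (Phred+33). The model
deliberately has no indels and no quality-dependent miscall structure;
conclusions about indel-sensitive tools do not transfer. All randomness
derives from one explicit seed per invocation, and identical seeds give
byte-identical FASTQ output.

`generate_mock_assembly()` plants labelled artifacts — faithful copies,
two-genome chimeras, truncations, and duplicate clusters (n copies with
per-copy truncation and point-mutation) — so the evaluator and the
duplicate-network detector can be tested against exact ground truth.
`remove_duplicate_reads()` drops exact `(read1, read2)` duplicates,
keeping first occurrences.

What the generator does *not* emulate: amplification chimera formation,
strain-level micro-diversity, coverage waviness along genomes, adapter or
quality artefacts. Passing tests therefore demonstrate correctness of the
algorithms under controlled conditions, not performance claims on any
particular real library.

## The assembly evaluator

Scaffolds at least 500 nt long are aligned to the truth genomes with a
built-in near-identity aligner: exact k-mer anchors (k = 31 by default),
chained along shared diagonals into maximal gap-free blocks whose
identity is computed by direct base comparison; both strands are
searched, circular genomes are aligned against their self-concatenation
with coordinates reported modulo length, and blocks under 95% identity
are suppressed. At the identities this evaluator targets (simulated or
plantedly mutated data, >= 95%) the gap-free blocks are exact;
`load_alignment_coords()` accepts show-coords-style tabular output from
an external whole-genome aligner when indel-tolerant blocks are wanted.

`classify_scaffold()` calls a scaffold **correct** when same-strand,
collinear blocks to a single genome cover at least 95% of it. The
coverage and collinearity thresholds are a design choice — the notion of
"correctly mapped" admits several operationalisations — mirroring the
stringent 0.95 length/similarity fractions commonly used for read
mapping in this setting. Misassemblies carry a reason: `multi-genome`
(chimera), `non-collinear` (rearranged single-genome joins),
`low-coverage` (novel or junk sequence attached), or `over-length`. The
over-length rule applies in *fragment mode*, when the truth templates are
known fixed-length fragments: allowing 5% over-length, any scaffold at or
above `1.05 x fragment length` (2.1 kb for 2 kb fragments) cannot derive
from one template and is misassembled unconditionally.

Summaries report per-size-bin counts with misassembly percentages
(rounded to integers; counts are exact), N50 (largest L such that
sequences >= L sum to at least half the total), maximum scaffold length,
correctly assembled length, and genome accounting: a genome is **hit**
when it receives any retained block, and **recovered** when a *single*
correct scaffold assigned to it covers at least 90% of the genome length
(wrap-around counted once for circular genomes). The single-sequence
requirement is the point — multi-scaffold representation forces further
assembly steps that can create chimeras; the 90% fraction is
configurable since "recovered into one sequence" fixes no threshold by
itself. Whether a "hit" should require the 95% block identity is equally
open; hits are tied to retained blocks here so that both statistics rest
on the same evidence.

`map_reads_back()` places reads on scaffolds end-to-end by exact k-mer
anchoring plus gap-free verification and reports the pair concordance
triple (percent concordant, percent multi-placed on one scaffold,
percent placed on different scaffolds), the read-level complement to the
scaffold-level statistics.

## Duplicate-contig networks

`pairwise_near_identity()` performs the all-vs-all comparison: candidate
pairs are screened by shared 21-mers (both strands, every 5th query k-mer
sampled), then verified by chained-anchor alignment with direct base
comparison, extending each block gap-free to the first mismatch; chains
across nearby diagonals absorb small indels. A pair becomes an edge when
identity >= 98% over >= 90% of the shorter contig — an operationalisation
of "nearly identical" chosen once and exposed as parameters, since
observed assembler duplicates sit near 100% identity and the exact
cut-off is not critical for well-separated clusters.
`connected_components()` (via igraph) returns the duplicate clusters,
each represented by its longest member — the copy most likely to be the
complete reconstruction. `flag_high_coverage()` applies the
complementary single-copy criterion: mean read coverage strictly above
5000.

`partition_reads()` splits a read-placement table into per-cluster read
sets plus the unassigned remainder — the input for cluster-specific
reassembly — guaranteeing a disjoint cover; a read hitting two clusters
goes to its best-scoring placement and the ambiguity is counted.
`deduplicate_cluster()` reduces a cluster to the distinct sequences it
really represents: members in descending length order are dropped when
contained (>= 98% identity over >= 90% of themselves) in an
already-retained member, leaving an antichain under containment.
Whether surviving duplicates are artifacts or true strain variants is
not decidable from sequence identity alone and is out of scope.

## Kingdom assignment and LCA

Each predicted protein carries the top hit per database: a viral RefSeq
screening subset, NCBI-nr, and RefSeq-P. The screening annotation calls
a protein viral when its bit score is strictly above 50. The final
kingdom call compares top-scoring hits across sources and applies the
first matching rule:

* **a** — the viral-subset hit scores *strictly* highest. A tie with a
  cellular database does not fire rule a (ties fall through to the other
  rules), keeping viral calls conservative.
* **d** — a protein-domain annotation is itself viral. Domain evidence is
  evaluated immediately after rule a so that it can rescue proteins the
  similarity search misses entirely.
* **b** — the best nr/RefSeq-P hit is taxonomically placed under Viruses
  with e-value < 1e-4 and bit score >= 45.
* **c** — as b, but the viral evidence is a keyword match: the subject
  title contains a term from the viral keyword dictionary
  (whole-token, case-insensitive).
* **putative-Viruses** — viral evidence by lineage or keyword exists but
  fails the confidence thresholds (e-value >= 1e-4, or bit < 45). This
  package treats a sub-threshold bit score the same as a failed e-value:
  weak viral evidence downgrades to putative rather than vanishing.
* **cellular** — otherwise the kingdom (Archaea/Bacteria/Eukaryota) of
  the best hit when e-value < 1e-4; else **unclassified**.

`build_keyword_dictionary()` constructs the keyword set from the subject
titles of proteins that won under rule a: lower-cased tokens of length
>= 3 minus a stoplist of generic terms (protein, hypothetical, putative,
uncharacterized, ...), plus two-word phrases recurring across titles.

`lca_assign()` reimplements the MEGAN-style placement at the parameters
used throughout this workflow: hits filtered to bit >= 45 and e-value
<= 1e-4, retention of hits within 10% of the best bit score, minimum
support 1, and assignment to the lowest common ancestor of all retained
taxa (LCA percent 100). `contamination_fraction()` computes the cellular
contamination screen: the percentage of distinct reads hitting an rRNA
reference at bit score >= 80, reported to two decimals.
`collate_contig_taxonomy()` aggregates protein calls per contig (majority
class, ties to unclassified; a contig is flagged viral when it encodes at
least one confirmed viral protein) alongside the nucleotide-level
kingdom for concordance checks.

One printed procedure is deliberately exposed as an *optional* filter and
left off by default: dropping viral calls on mixed contigs whose
screening score is under half the overall top score. Its published
description is ambiguous about the exact population it was applied to,
so it is not part of the default decision path.

## Circovirus-like genome annotation

`find_orfs()` scans all six frames; on circular sequences the doubled
sequence is scanned and coordinates are reported modulo length, so genes
crossing the origin are found and reported with `end < start`. Only
maximal ORFs (longest start per stop) above a length threshold are
reported; the standard genetic code with ATG starts is the default, and
reports use 1-based inclusive coordinates with signed frames, the
convention of published annotation tables.

`find_ori()` detects the rolling-circle replication origin architecture:
a conserved nonanucleotide-family core motif (defaults `AGTATTAC`,
`AGTATTAT`, `ATTATTAC`; IUPAC degenerate patterns accepted) presented in
the loop of a stem-loop. "Palindromic repeat" is interpreted as an
inverted repeat: two arms flanking the motif within a configurable gap
(<= 10 nt), the right arm equal to the reverse complement of the left up
to a mismatch budget; "imperfect" means >= 1 arm mismatch. Arm length is
counted per arm (not per stem): published 11/13/15 nt repeat annotations
are consistent with per-arm counting when the annotated interval spans
arm + motif + arm. The default minimum arm of 8 nt keeps the expected
number of chance arms per 2 kb below 0.05; the search wraps on circular
sequences, and the longest arm (fewest mismatches on ties) is reported
per motif occurrence.

`scan_rep_motifs()` ships three Rep motif I/II/III profile sets observed
across circovirus-like clades: `FTINN/HLQG/YCKKD`
(invertebrate-circovirus-like), the degenerate `H.Q` and `Y.KD`/`Y.KE`
class II/III pair typical of animal and bird circovirus Reps whose motif
I is often unrecognisable, and `FLTF/HLH/YCMKD` (geminivirus-like).
Patterns are position-wildcarded amino-acid strings; all (overlapping)
matches are reported.

## Numerical and testing choices

* Internal coordinates are 0-based half-open; all human-readable reports
  are 1-based inclusive.
* Anchor k = 31 for truth alignment (unique in the genome sizes used),
  k = 21 for duplicate screening (sensitive at 98% identity); chain gaps
  up to 300 nt bridge anchor dropouts caused by scattered substitutions.
* Ties: cluster representatives and dedup processing break length ties
  lexicographically; kingdom score ties across sources are resolved
  against rule a (above); LCA retention uses a closed
  `>= (1 - top/100) * best` band.
* Degenerate inputs: empty genome sets fragment to empty libraries;
  templates shorter than the read length are excluded with a warning;
  ORFs containing N are skipped with a warning; an empty hit table yields
  class unclassified.
* The test suite builds every fixture in code at fixed seeds. Problem
  sizes were chosen to exercise the algorithms well past boundary
  conditions while keeping the default run light: 10,000 read pairs for
  parameter-recovery checks, a 286-member planted duplicate cluster and
  a 135-contig containment scenario for the network module, 500 planted
  origin stem-loops, 200 random taxonomies against a brute-force LCA
  oracle, and 1,000 random length multisets against the cumulative-sum
  N50 definition.

## Known limitations

* The aligner is substitution-oriented; heavily indelled assemblies
  should be evaluated through imported show-coords blocks instead.
* The error model draws substitutions only; quality strings encode the
  ramp, not a learned profile.
* The evaluator's `correct`/`recovered` thresholds are declared
  operationalisations; results are only comparable across runs using the
  same parameter object.
* Strain variants and assembler duplicates are indistinguishable to the
  identity network by construction.
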