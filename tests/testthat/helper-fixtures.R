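# shared fixture builders and independent oracles

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force window enumerator: expected fragment count for one genome
oracle_fragment_count <- function(genome_len, fragment_length,
                                  keep_every_second) {
  starts <- integer(0)
  pos <- 0L
  idx <- 0L
  while (pos + fragment_length <= genome_len) {
    if (!keep_every_second || idx %% 2L == 0L) starts <- c(starts, pos)
    pos <- pos + fragment_length
    idx <- idx + 1L
  }
  length(starts)
}

# brute-force N50: largest L such that total length of sequences >= L is at
# least half the total
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  max(lengths[vapply(lengths, function(L) {
    sum(lengths[lengths >= L]) >= total / 2
  }, logical(1))])
}

# brute-force LCA: deepest node whose ancestor set contains every hit taxon
oracle_lca <- function(taxonomy, nodes) {
  paths <- lapply(nodes, function(n) {
    path <- integer(0)
    cur <- n
    repeat {
      path <- c(path, cur)
      p <- taxonomy$parent_of[[as.character(cur)]]
      if (p == cur) break
      cur <- p
    }
    path
  })
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(n) length(oracle_ancestors(taxonomy, n)),
                   integer(1))
  common[which.max(depths)]
}

oracle_ancestors <- function(taxonomy, n) {
  path <- integer(0)
  cur <- n
  repeat {
    path <- c(path, cur)
    p <- taxonomy$parent_of[[as.character(cur)]]
    if (p == cur) break
    cur <- p
  }
  path
}

# brute-force sliding-window wildcard matcher for protein motifs
oracle_motif_positions <- function(protein, pattern) {
  pl <- nchar(pattern)
  n <- nchar(protein)
  if (n < pl) return(integer(0))
  pc <- strsplit(pattern, "")[[1]]
  out <- integer(0)
  for (i in seq_len(n - pl + 1L)) {
    win <- strsplit(substr(protein, i, i + pl - 1L), "")[[1]]
    if (all(pc == "." | pc == win)) out <- c(out, i)
  }
  out
}

# random taxonomy: node 1 is the root; each later node parents to a
# uniformly drawn earlier node
random_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  parent <- c(1L, vapply(2:n_nodes, function(i) {
    sample.int(i - 1L, 1L)
  }, integer(1)))
  taxonomy_tree(seq_len(n_nodes), parent)
}

# a genome set with one planted duplicate-cluster mock assembly
make_duplicate_mock <- function(n_copies, mutation_rate = 0.005,
                                max_truncation = 0.1, genome_len = 2000,
                                seed = 7) {
  g <- random_genomes(1, genome_len, seed = seed, prefix = "base")
  plan <- mock_assembly_plan(
    duplicate_cluster = data.frame(genome = "base1", n = n_copies,
                                   max_truncation = max_truncation,
                                   mutation_rate = mutation_rate),
    seed = seed + 1L)
  generate_mock_assembly(g, plan)
}

viral_dict <- build_keyword_dictionary(c(
  "phage portal protein", "terminase large subunit",
  "phage capsid protein", "phage-integrase"
))

# the hand-derived rule fixture: one protein per decision branch
kingdom_fixture <- function() {
  h <- function(p, src, title, lin, bit, ev) {
    protein_hits(p, src, title, lin, bit, ev)
  }
  hits <- rbind(
    h("p01", "viral-subset", "gp23 major capsid", "Viruses", 120, 1e-20),
    h("p01", "nr", "ABC transporter", "Bacteria", 100, 1e-15),
    h("p02", "nr", "hypothetical protein", "Viruses; Caudovirales", 100, 1e-6),
    h("p03", "nr", "putative phage terminase", "Bacteria", 100, 1e-6),
    h("p04", "nr", "ABC transporter", "Bacteria", 90, 1e-9),
    h("p05", "nr", "hypothetical protein", "Viruses", 100, 1e-3),
    h("p06", "nr", "putative phage terminase", "Bacteria", 100, 1e-3),
    h("p07", "nr", "ABC transporter", "Bacteria", 100, 1e-6),
    h("p08", "refseq-p", "ABC transporter", "Archaea", 90, 1e-6),
    h("p09", "nr", "tubulin", "Eukaryota", 80, 1e-6),
    h("p11", "nr", "ABC transporter", "Bacteria", 60, 1e-3),
    h("p12", "viral-subset", "gp5 baseplate", "Viruses", 100, 1e-9),
    h("p12", "nr", "hypothetical protein", "Viruses", 100, 1e-9),
    h("p13", "viral-subset", "gp5 baseplate", "Viruses", 100, 1e-9),
    h("p13", "nr", "ABC transporter", "Bacteria", 100, 1e-9),
    h("p14", "viral-subset", "gp20 portal", "Viruses", 60, 1e-8),
    h("p15", "nr", "hypothetical protein", "Viruses", 40, 1e-6),
    h("p16", "nr", "putative phage terminase", "Bacteria", 100, 1e-4),
    h("p17", "nr", "hypothetical protein", "Viruses", 100, 1e-4),
    h("p18", "viral-subset", "weak match", "Viruses", 50, 1e-5),
    h("p18", "nr", "ABC transporter", "Bacteria", 100, 1e-6),
    h("p19", "refseq-p", "hypothetical protein", "Viruses; Microviridae",
      95, 1e-12)
  )
  domains <- data.frame(
    protein_id = c("p04", "p20"),
    accession = c("PF04860", "PF00005"),
    description = c("phage portal protein", "ABC transporter"),
    viral_flag = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  truth <- c(
    p01 = "Viruses",          # a: viral-subset strictly highest
    p02 = "Viruses",          # b: viral lineage, confident
    p03 = "Viruses",          # c: viral keyword, confident
    p04 = "Viruses",          # d: viral domain
    p05 = "putative-Viruses", # viral lineage, e-value too high
    p06 = "putative-Viruses", # viral keyword, e-value too high
    p07 = "Bacteria",
    p08 = "Archaea",
    p09 = "Eukaryota",
    p10 = "unclassified",     # no evidence at all
    p11 = "unclassified",     # cellular hit above the e-value threshold
    p12 = "Viruses",          # score tie: a does not fire, b does
    p13 = "Bacteria",         # score tie, no other viral evidence
    p14 = "Viruses",          # only a viral-subset hit: a
    p15 = "putative-Viruses", # viral lineage but bit below 45
    p16 = "putative-Viruses", # keyword at e-value exactly 1e-4: not confident
    p17 = "putative-Viruses", # lineage at e-value exactly 1e-4
    p18 = "Bacteria",         # viral-subset not highest
    p19 = "Viruses",          # b via RefSeq-P
    p20 = "unclassified"      # non-viral domain only
  )
  rules <- c(p01 = "a", p02 = "b", p03 = "c", p04 = "d", p12 = "b",
             p13 = "cellular", p14 = "a", p19 = "b")
  list(hits = hits, domains = domains, truth = truth, rules = rules)
}
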