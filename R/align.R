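# Near-identity alignment by exact k-mer anchoring.
#
# Assembled scaffolds and their source genomes differ only by scattered
# substitutions at the identities of interest (>= 95%), so a seed-and-extend
# aligner with gap-free per-diagonal chaining recovers the alignment blocks
# exactly: shared k-mers are anchors, anchors on a common diagonal are chained
# into maximal blocks, and block identity is computed by direct base
# comparison over the chained span.

# k-mer index over a genome set; circular genomes are self-concatenated so
# blocks may cross the origin. Returns data.table(genome, gpos, kmer) with
# gpos 0-based on the (possibly doubled) sequence.
genome_kmer_index <- function(genomes, k) {
  if (k > min(nchar(genomes$sequence))) {
    stop("min_anchor k exceeds the shortest genome length")
  }
  idx <- lapply(seq_len(nrow(genomes)), function(i) {
    s <- genomes$sequence[i]
    if (genomes$circular[i]) s <- paste0(s, s)
    kt <- kmerize(s, k)
    kt[, genome := genomes$id[i]]
    kt
  })
  data.table::rbindlist(idx)
}

# chain anchors sharing a diagonal into maximal blocks; anchors is a
# data.table with columns spos, gpos (0-based); returns data.table of spans
chain_diagonal <- function(spos, k, chain_gap) {
  spos <- sort(spos)
  brk <- c(0L, which(diff(spos) > chain_gap), length(spos))
  data.table::data.table(
    s_start = spos[brk[-length(brk)] + 1L],
    s_end = spos[brk[-1L]] + k
  )
}

#' Align scaffolds to truth genomes by exact k-mer anchoring
#'
#' Both strands are searched; circular genomes are aligned against their
#' self-concatenation with coordinates reported modulo genome length. Blocks
#' below `min_block_identity` are suppressed.
#'
#' @param scaffolds a `genome_set` of assembled sequences.
#' @param genomes a `genome_set` of truth genomes.
#' @param min_block_identity minimum percent identity of an emitted block.
#' @param min_anchor anchor k-mer size; must not exceed the shortest genome.
#' @param chain_gap maximum gap (nt) between co-diagonal anchors chained into
#'   one block.
#' @return data.frame of alignment blocks: scaffold_id, genome_id, s_start,
#'   s_end, g_start, g_end (0-based half-open; genome coordinates modulo
#'   genome length for circular genomes), strand, identity (percent).
#' @export
align_scaffolds_to_truth <- function(scaffolds, genomes,
                                     min_block_identity = 95,
                                     min_anchor = 31L, chain_gap = 300L) {
  if (!nrow(genomes)) stop("genome set is empty")
  k <- as.integer(min_anchor)
  idx <- genome_kmer_index(genomes, k)
  data.table::setkey(idx, kmer)
  glen <- setNames(nchar(genomes$sequence), genomes$id)
  gseq_ext <- setNames(ifelse(genomes$circular,
                              paste0(genomes$sequence, genomes$sequence),
                              genomes$sequence), genomes$id)
  out <- list()
  for (i in seq_len(nrow(scaffolds))) {
    sid <- scaffolds$id[i]
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") scaffolds$sequence[i] else
        revcomp(scaffolds$sequence[i])
      slen <- nchar(sseq)
      if (slen < k) next
      skt <- kmerize(sseq, k)
      data.table::setnames(skt, "pos", "spos")
      anchors <- idx[skt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (!nrow(anchors)) next
      anchors[, diag := pos - spos]
      blocks <- anchors[, chain_diagonal(spos, k, chain_gap),
                        by = .(genome, diag)]
      # identity by direct comparison over each chained span
      blocks[, `:=`(g_start = s_start + diag, g_end = s_end + diag)]
      ident <- vapply(seq_len(nrow(blocks)), function(j) {
        a <- substr(sseq, blocks$s_start[j] + 1L, blocks$s_end[j])
        b <- substr(gseq_ext[[blocks$genome[j]]],
                    blocks$g_start[j] + 1L, blocks$g_end[j])
        100 * str_matches(a, b) / nchar(a)
      }, numeric(1))
      blocks[, identity := ident]
      blocks <- blocks[identity >= min_block_identity]
      if (!nrow(blocks)) next
      # back to original scaffold coordinates for the minus strand
      if (strand == "-") {
        tmp <- blocks$s_start
        blocks[, s_start := slen - s_end]
        blocks[, s_end := slen - tmp]
      }
      blocks[, `:=`(scaffold_id = sid, strand = strand)]
      out[[length(out) + 1L]] <- blocks
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold_id = character(0), genome_id = character(0),
                      s_start = integer(0), s_end = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- data.table::rbindlist(out)
  # normalise circular coordinates modulo genome length and drop the
  # duplicate blocks arising from the doubled sequence
  res[, L := glen[genome]]
  res <- res[s_end - s_start <= L]
  res[, `:=`(g_start = g_start %% L, g_end = NULL)]
  res[, g_end := g_start + (s_end - s_start)]
  res <- unique(res, by = c("scaffold_id", "genome", "strand",
                            "s_start", "s_end", "g_start"))
  # doubling a circular genome can re-discover pieces of one block on the
  # same modular diagonal; keep only the maximal block per diagonal
  res[, mdiag := (g_start - s_start) %% L]
  data.table::setorder(res, scaffold_id, genome, strand, mdiag,
                       s_start, -s_end)
  res[, keep := {
    maxend <- cummax(c(-1L, head(s_end, -1L)))
    s_end > maxend
  }, by = .(scaffold_id, genome, strand, mdiag)]
  res <- res[keep == TRUE]
  data.frame(scaffold_id = res$scaffold_id, genome_id = res$genome,
             s_start = res$s_start, s_end = res$s_end,
             g_start = res$g_start, g_end = res$g_end,
             strand = res$strand, identity = res$identity,
             stringsAsFactors = FALSE)
}

#' Load alignment blocks from a show-coords style tabular file
#'
#' Accepts the whitespace-separated tabular dialect produced by
#' `show-coords -T -l -c`: reference (genome) start/end, query (scaffold)
#' start/end, lengths, percent identity, then trailing reference and query
#' name tags. Input coordinates are 1-based inclusive; the returned blocks
#' use the package's 0-based half-open convention, with strand inferred from
#' coordinate order.
#'
#' @param path file path.
#' @return data.frame of alignment blocks (as [align_scaffolds_to_truth()]).
#' @export
load_alignment_coords <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # header/separator lines (NUCMER banner, column headers) are non-numeric
  keep <- grepl("^\\s*[0-9]", lines)
  lines <- lines[keep]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 9) stop("malformed show-coords row at data line ", i)
    v <- suppressWarnings(as.numeric(f[1:7]))
    if (anyNA(v)) stop("malformed show-coords row at data line ", i)
    gs <- v[1]; ge <- v[2]; ss <- v[3]; se <- v[4]
    strand <- if ((ge - gs) * (se - ss) < 0) "-" else "+"
    data.frame(
      scaffold_id = f[length(f)], genome_id = f[length(f) - 1L],
      s_start = min(ss, se) - 1, s_end = max(ss, se),
      g_start = min(gs, ge) - 1, g_end = max(gs, ge),
      strand = strand, identity = v[7], stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(scaffold_id = character(0), genome_id = character(0),
                      s_start = integer(0), s_end = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
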