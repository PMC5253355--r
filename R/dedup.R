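# Network-based detection of near-identical contigs.
#
# Assemblers presented with excessively covered templates (e.g. small
# circular genomes after rolling-circle amplification) can emit many
# near-identical copies and sub-sequences of one underlying sequence.
# These are found by all-vs-all near-identity comparison, clustered as
# connected components of the resulting identity graph, and the reads
# mapping to each cluster partitioned out for separate reassembly.

#' All-vs-all near-identity edges between contigs
#'
#' Candidate pairs are screened by shared k-mers (both strands), then
#' verified by a gap-tolerant chained-anchor alignment of the shorter
#' against the longer contig: anchors on common diagonals form gap-free
#' blocks whose bases are compared directly, and block chains across nearby
#' diagonals absorb small indels. An edge is emitted iff the aligned
#' identity reaches `min_identity` over at least `min_fraction` of the
#' shorter contig.
#'
#' @param contigs a `genome_set`.
#' @param k screening k-mer size (>= 11).
#' @param min_identity minimum percent identity (default 98).
#' @param min_fraction minimum aligned fraction of the shorter contig
#'   (default 0.9).
#' @param chain_gap maximum gap between chained co-diagonal anchors.
#' @param screen_step sample every `screen_step`-th query k-mer during
#'   screening; base-level verification is unaffected.
#' @return data.frame of edges: contig_a, contig_b, identity, fraction
#'   (symmetric relation stored once with contig_a < contig_b).
#' @export
pairwise_near_identity <- function(contigs, k = 21L, min_identity = 98,
                                   min_fraction = 0.9, chain_gap = 300L,
                                   screen_step = 5L) {
  if (k < 11L) stop("k must be >= 11")
  if (nrow(contigs) < 2L) {
    return(empty_edges())
  }
  ids <- contigs$id
  lens <- setNames(nchar(contigs$sequence), ids)
  fwd_int <- setNames(lapply(contigs$sequence, utf8ToInt), ids)
  rc_int <- setNames(lapply(revcomp(contigs$sequence), utf8ToInt), ids)
  idx <- genome_kmer_index_safe(contigs, k)
  data.table::setnames(idx, c("pos", "genome"), c("gpos", "t"))
  data.table::setkey(idx, kmer)
  edges <- list()
  for (strand in c("+", "-")) {
    qk <- data.table::rbindlist(lapply(seq_along(ids), function(i) {
      s <- if (strand == "+") contigs$sequence[i] else
        intToUtf8(rc_int[[i]])
      kt <- kmerize(s, k, step = screen_step)
      if (nrow(kt)) kt[, q := ids[i]]
      kt
    }))
    if (!nrow(qk)) next
    data.table::setnames(qk, "pos", "spos")
    anchors <- idx[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    anchors <- anchors[t > q]  # each unordered pair evaluated once
    if (!nrow(anchors)) next
    anchors[, `:=`(kmer = NULL, diag = gpos - spos)]
    data.table::setorder(anchors, q, t, diag, spos)
    new_block <- c(TRUE, anchors$q[-1] != anchors$q[-nrow(anchors)] |
                     anchors$t[-1] != anchors$t[-nrow(anchors)] |
                     anchors$diag[-1] != anchors$diag[-nrow(anchors)] |
                     diff(anchors$spos) > chain_gap)
    anchors[, block := cumsum(new_block)]
    blocks <- anchors[, .(q = q[1], t = t[1], diag = diag[1],
                          s_start = spos[1], s_end = spos[.N] + k),
                      by = block]
    qint <- if (strand == "+") fwd_int else rc_int
    stats <- blocks[, verify_pair(s_start, s_end, diag,
                                  qint[[q[1]]], fwd_int[[t[1]]]),
                    by = .(q, t)]
    stats <- stats[aligned > 0]
    if (!nrow(stats)) next
    stats[, strand := strand]
    edges[[length(edges) + 1L]] <- stats
  }
  if (!length(edges)) return(empty_edges())
  e <- data.table::rbindlist(edges)
  data.table::setnames(e, c("q", "t"), c("contig_a", "contig_b"))
  # fraction is relative to the shorter contig of the pair
  e[, shorter := pmin(lens[contig_a], lens[contig_b])]
  e[, fraction := pmin(1, aligned / shorter)]
  # best strand per pair
  data.table::setorder(e, contig_a, contig_b, -fraction, -identity)
  e <- unique(e, by = c("contig_a", "contig_b"))
  e <- e[identity >= min_identity & fraction >= min_fraction]
  data.frame(contig_a = e$contig_a, contig_b = e$contig_b,
             identity = e$identity, fraction = e$fraction,
             stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(contig_a = character(0), contig_b = character(0),
             identity = numeric(0), fraction = numeric(0),
             stringsAsFactors = FALSE)
}

# verify one candidate pair from its chained blocks (0-based half-open
# query spans and their diagonals): extend each block gap-free to the first
# mismatch, compare bases directly, and aggregate matches over the union of
# query spans (largest blocks first, overlap counted once). qi/ti are
# utf8ToInt-encoded query and target sequences.
verify_pair <- function(s_start, s_end, diag, qi, ti) {
  ord <- order(s_start - s_end)  # largest first
  qlen <- length(qi); tlen <- length(ti)
  covered <- logical(qlen)
  matches <- 0; aligned <- 0
  for (j in ord) {
    s0 <- s_start[j]; s1 <- s_end[j]
    g0 <- s0 + diag[j]; g1 <- s1 + diag[j]
    if (g0 < 0 || g1 > tlen) next
    # gap-free extension of the chained span to the first mismatch
    while (s0 > 0 && g0 > 0 && qi[s0] == ti[g0]) {
      s0 <- s0 - 1L; g0 <- g0 - 1L
    }
    while (s1 < qlen && g1 < tlen && qi[s1 + 1L] == ti[g1 + 1L]) {
      s1 <- s1 + 1L; g1 <- g1 + 1L
    }
    span <- (s0 + 1L):s1
    new <- !covered[span]
    if (!any(new)) next
    eq <- qi[span] == ti[(g0 + 1L):g1]
    matches <- matches + sum(eq[new])
    aligned <- aligned + sum(new)
    covered[span] <- TRUE
  }
  if (aligned == 0) {
    return(data.table::data.table(identity = numeric(0),
                                  aligned = integer(0)))
  }
  data.table::data.table(identity = 100 * matches / aligned,
                         aligned = as.integer(aligned))
}

#' Cluster contigs by connected components of the identity graph
#'
#' @param edges edge data.frame from [pairwise_near_identity()].
#' @param all_contig_ids character vector of every contig id (edge endpoints
#'   must be a subset); singletons are suppressed from the cluster list.
#' @param contig_lengths optional named lengths used to pick the
#'   representative (longest member, ties broken lexicographically).
#' @return list of clusters, each a list(members, representative).
#' @export
connected_components <- function(edges, all_contig_ids,
                                 contig_lengths = NULL) {
  bad <- setdiff(unique(c(edges$contig_a, edges$contig_b)), all_contig_ids)
  if (length(bad)) stop("edge endpoints not in all_contig_ids: ",
                        paste(bad, collapse = ", "))
  if (!nrow(edges)) return(list())
  g <- igraph::graph_from_data_frame(edges[, c("contig_a", "contig_b")],
                                     directed = FALSE,
                                     vertices = all_contig_ids)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- sort(names(comp$membership)[comp$membership == ci])
    if (length(members) < 2L) next
    rep_id <- if (!is.null(contig_lengths)) {
      ml <- contig_lengths[members]
      members[order(-ml, members)][1]
    } else members[1]
    out[[length(out) + 1L]] <- list(members = members,
                                    representative = rep_id)
  }
  out
}

#' Flag contigs with excessive read coverage
#'
#' @param coverage named numeric vector: contig id -> mean read coverage
#'   (reads x read length / contig length).
#' @param threshold coverage threshold; contigs strictly above it are
#'   flagged (default 5000).
#' @return character vector of flagged ids, by descending coverage.
#' @export
flag_high_coverage <- function(coverage, threshold = 5000) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (!length(coverage)) return(character(0))
  flagged <- coverage[coverage > threshold]
  names(flagged)[order(-flagged)]
}

#' Partition reads by the contig cluster they map to
#'
#' A read is assigned to a cluster when any of its placements hits a cluster
#' member; reads hitting no cluster go to `unassigned`. A read hitting more
#' than one cluster is assigned to the cluster of its best-scoring
#' placement (ties: first cluster by representative id) and the event is
#' counted in `n_ambiguous`.
#'
#' @param placements data.frame(read_id, contig_id, score); score optional
#'   (defaults to 0).
#' @param clusters cluster list from [connected_components()].
#' @param all_read_ids optional universe of read ids; reads absent from the
#'   placement table are unassigned.
#' @return list with `cluster_reads` (list of read-id vectors, one per
#'   cluster, named by representative), `unassigned` (read-id vector) and
#'   `n_ambiguous`.
#' @export
partition_reads <- function(placements, clusters, all_read_ids = NULL) {
  reads <- unique(c(placements$read_id, all_read_ids))
  if (is.null(placements$score)) placements$score <- 0
  member_to_cluster <- list()
  reps <- vapply(clusters, `[[`, character(1), "representative")
  ord <- order(reps)
  clusters <- clusters[ord]; reps <- reps[ord]
  cl_of <- unlist(lapply(seq_along(clusters), function(i) {
    setNames(rep(i, length(clusters[[i]]$members)), clusters[[i]]$members)
  }))
  pl <- placements
  pl$cluster <- cl_of[pl$contig_id]
  hit <- pl[!is.na(pl$cluster), , drop = FALSE]
  assigned <- character(0)
  cluster_reads <- rep(list(character(0)), length(clusters))
  names(cluster_reads) <- reps
  n_ambiguous <- 0L
  if (nrow(hit)) {
    # best placement per read: highest score, then first cluster in
    # representative order
    hit <- hit[order(hit$read_id, -hit$score, hit$cluster), , drop = FALSE]
    per_read_n <- tapply(hit$cluster, hit$read_id,
                         function(x) length(unique(x)))
    n_ambiguous <- sum(per_read_n > 1L)
    best <- hit[!duplicated(hit$read_id), , drop = FALSE]
    for (i in seq_along(clusters)) {
      cluster_reads[[i]] <- best$read_id[best$cluster == i]
    }
    assigned <- best$read_id
  }
  list(cluster_reads = cluster_reads,
       unassigned = setdiff(reads, assigned),
       n_ambiguous = n_ambiguous)
}

#' Reduce a cluster to its non-contained members
#'
#' Members are processed in descending length; a member is dropped when it
#' is contained in an already-retained longer member (>= `min_identity`
#' percent identity over >= `min_fraction` of itself). The retained set is
#' an antichain under containment: the distinct sequences a cluster of
#' assembly duplicates really represents.
#'
#' @param cluster a cluster (list with `members`) or a character vector of
#'   member ids.
#' @param contigs a `genome_set` holding the member sequences.
#' @param min_identity containment identity threshold (default 98).
#' @param min_fraction fraction of the shorter member that must align
#'   (default 0.9).
#' @param k screening k-mer size.
#' @return character vector of retained contig ids.
#' @export
deduplicate_cluster <- function(cluster, contigs, min_identity = 98,
                                min_fraction = 0.9, k = 21L) {
  members <- if (is.list(cluster)) cluster$members else cluster
  stopifnot(all(members %in% contigs$id))
  sub <- contigs[match(members, contigs$id), , drop = FALSE]
  sub <- sub[order(-nchar(sub$sequence), sub$id), , drop = FALSE]
  retained <- character(0)
  for (i in seq_len(nrow(sub))) {
    if (!length(retained)) {
      retained <- sub$id[i]
      next
    }
    pool <- genome_set(
      c(sub$id[i], retained),
      c(sub$sequence[i], contigs$sequence[match(retained, contigs$id)])
    )
    e <- pairwise_near_identity(pool, k = k, min_identity = min_identity,
                                min_fraction = min_fraction)
    contained <- any((e$contig_a == sub$id[i] | e$contig_b == sub$id[i]) &
                       e$fraction >= min_fraction)
    if (!contained) retained <- c(retained, sub$id[i])
  }
  sort(retained)
}
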