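#' Evaluation parameters for assembly assessment
#'
#' Defaults mirror stringent virome assembly benchmarking practice: scaffolds
#' under 500 nt are ignored, alignment blocks must reach 95% identity, a
#' scaffold is "correct" when collinear blocks to a single genome cover 95%
#' of it, and a genome is "recovered" when one correct scaffold covers 90%
#' of the genome. In fragment mode a 5% over-length allowance is applied on
#' top of the fragment length.
#'
#' @param min_scaffold_length minimum scaffold length retained (nt).
#' @param min_block_identity minimum block percent identity.
#' @param correct_coverage_fraction scaffold coverage needed for "correct".
#' @param recovery_fraction genome coverage needed for "recovered".
#' @param overlength_fraction allowed over-length above the fragment length
#'   in fragment mode.
#' @param size_bins data.frame(lo, hi, label) of disjoint ordered length bins
#'   covering `[min_scaffold_length, Inf)`; default is the whole-genome
#'   binning (500-999 nt up to >= 200 kb).
#' @param min_anchor anchor k-mer size for the built-in aligner.
#' @return an `eval_params` list.
#' @export
eval_params <- function(min_scaffold_length = 500L,
                        min_block_identity = 95,
                        correct_coverage_fraction = 0.95,
                        recovery_fraction = 0.90,
                        overlength_fraction = 0.05,
                        size_bins = default_size_bins(min_scaffold_length),
                        min_anchor = 31L) {
  stopifnot(all(diff(size_bins$lo) > 0), all(size_bins$lo < size_bins$hi))
  structure(list(min_scaffold_length = as.integer(min_scaffold_length),
                 min_block_identity = min_block_identity,
                 correct_coverage_fraction = correct_coverage_fraction,
                 recovery_fraction = recovery_fraction,
                 overlength_fraction = overlength_fraction,
                 size_bins = size_bins,
                 min_anchor = as.integer(min_anchor)),
            class = "eval_params")
}

#' Default scaffold size bins
#'
#' @param min_len lower bound of the first bin.
#' @return data.frame(lo, hi, label); hi is exclusive.
#' @export
default_size_bins <- function(min_len = 500L) {
  lo <- c(min_len, 1e3, 2e3, 5e3, 1e4, 2e4, 5e4, 1e5, 2e5)
  hi <- c(lo[-1], Inf)
  label <- c(sprintf("%d-999 nt", min_len), "1-1.999 kb", "2-4.999 kb",
             "5-9.999 kb", "10-19.999 kb", "20-49.999 kb", "50-99.999 kb",
             "100-199.999 kb", ">=200 kb")
  data.frame(lo = lo, hi = hi, label = label, stringsAsFactors = FALSE)
}

#' Size bins for fragment-mode evaluation
#'
#' When the truth templates are fixed-length fragments, the informative bins
#' sit below the over-length cutoff, with one terminal bin collecting every
#' scaffold at or above it.
#'
#' @param fragment_length fragment length (nt).
#' @param overlength_fraction allowed over-length fraction.
#' @param min_len lower bound of the first bin.
#' @return data.frame(lo, hi, label).
#' @export
fragment_size_bins <- function(fragment_length = 2000L,
                               overlength_fraction = 0.05,
                               min_len = 500L) {
  cutoff <- overlength_cutoff(fragment_length, overlength_fraction)
  lo <- c(min_len, 1000, 1500, cutoff)
  hi <- c(lo[-1], Inf)
  label <- c(sprintf("%d-999 nt", min_len), "1000-1499 nt",
             sprintf("1500-%d nt", cutoff - 1L), sprintf(">=%d nt", cutoff))
  data.frame(lo = lo, hi = hi, label = label, stringsAsFactors = FALSE)
}

#' Over-length misassembly cutoff in fragment mode
#'
#' The smallest scaffold length classified as over-length misassembled when
#' the truth templates all have length `fragment_length`: scaffolds at or
#' above `(1 + overlength_fraction) * fragment_length` cannot derive from a
#' single template.
#'
#' @param fragment_length template length (nt).
#' @param overlength_fraction allowed over-length fraction (default 0.05).
#' @return cutoff length in nt.
#' @export
overlength_cutoff <- function(fragment_length, overlength_fraction = 0.05) {
  as.integer(ceiling((1 + overlength_fraction) * fragment_length))
}

# union length of 0-based half-open intervals
interval_union_len <- function(start, end) {
  if (!length(start)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(ir))
}

# coverage of a circle of length L by intervals that may wrap (end > L)
circular_union_len <- function(start, end, L) {
  wrap <- end > L
  s <- c(start, rep(0, sum(wrap)))
  e <- c(pmin(end, L), end[wrap] - L)
  min(interval_union_len(s, e), L)
}

#' Classify one scaffold as correct, misassembled or unaligned
#'
#' In fragment mode (non-NULL `fragment_mode_length`) any scaffold at or
#' above the over-length cutoff is misassembled outright. Otherwise a
#' scaffold is correct when same-strand, collinear blocks to one genome
#' cover at least `correct_coverage_fraction` of it; conflicting evidence
#' yields a misassembly reason of multi-genome, non-collinear or
#' low-coverage; no blocks yields unaligned.
#'
#' @param scaffold_id scaffold identifier.
#' @param scaffold_length scaffold length (nt).
#' @param blocks alignment blocks for this scaffold.
#' @param params an [eval_params()].
#' @param fragment_mode_length truth fragment length, or NULL.
#' @return one-row data.frame: scaffold_id, length, status, genome_id,
#'   covered_fraction, reason.
#' @export
classify_scaffold <- function(scaffold_id, scaffold_length, blocks,
                              params = eval_params(),
                              fragment_mode_length = NULL) {
  verdict <- function(status, genome = NA_character_, cov = 0, reason = "none") {
    data.frame(scaffold_id = scaffold_id, length = scaffold_length,
               status = status, genome_id = genome, covered_fraction = cov,
               reason = reason, stringsAsFactors = FALSE)
  }
  if (!is.null(fragment_mode_length) &&
      scaffold_length >= overlength_cutoff(fragment_mode_length,
                                           params$overlength_fraction)) {
    return(verdict("misassembled", reason = "over-length"))
  }
  if (is.null(blocks) || !nrow(blocks)) return(verdict("unaligned"))
  blocks <- blocks[blocks$scaffold_id == scaffold_id, , drop = FALSE]
  if (!nrow(blocks)) return(verdict("unaligned"))
  per_genome <- split(blocks, blocks$genome_id)
  best_g <- NA_character_; best_cov <- 0; any_conflict <- FALSE
  for (g in names(per_genome)) {
    b <- per_genome[[g]]
    b <- b[order(b$s_start), , drop = FALSE]
    same_strand <- length(unique(b$strand)) == 1L
    coll <- same_strand && (
      if (b$strand[1] == "+") !is.unsorted(b$g_start)
      else !is.unsorted(rev(b$g_start))
    )
    cov <- interval_union_len(b$s_start, b$s_end) / scaffold_length
    if (!coll) any_conflict <- TRUE
    if (coll && cov > best_cov) {
      best_cov <- cov; best_g <- g
    }
  }
  if (!is.na(best_g) && best_cov >= params$correct_coverage_fraction) {
    return(verdict("correct", genome = best_g, cov = best_cov))
  }
  if (length(per_genome) >= 2L) {
    return(verdict("misassembled", cov = best_cov, reason = "multi-genome"))
  }
  if (any_conflict) {
    return(verdict("misassembled", cov = best_cov, reason = "non-collinear"))
  }
  verdict("misassembled", cov = best_cov, reason = "low-coverage")
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L sum to at least
#' half the total length.
#'
#' @param lengths positive numeric vector.
#' @return the N50 value.
#' @export
compute_n50 <- function(lengths) {
  if (!length(lengths)) stop("lengths must be non-empty")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Genomes hit and genomes recovered
#'
#' A genome is "hit" when it receives at least one alignment block from any
#' scaffold; "recovered" when at least one single correct scaffold assigned
#' to it covers at least `recovery_fraction` of the genome length (circular
#' genomes: wrap-around coverage counted once).
#'
#' @param verdicts data.frame of scaffold verdicts.
#' @param blocks data.frame of alignment blocks.
#' @param genomes the truth `genome_set`.
#' @param params an [eval_params()].
#' @return list with `hit` and `recovered` id character vectors.
#' @export
genomes_hit_and_recovered <- function(verdicts, blocks, genomes,
                                      params = eval_params()) {
  hit <- intersect(genomes$id, unique(blocks$genome_id))
  glen <- setNames(nchar(genomes$sequence), genomes$id)
  gcirc <- setNames(genomes$circular, genomes$id)
  recovered <- character(0)
  correct <- verdicts[verdicts$status == "correct", , drop = FALSE]
  for (i in seq_len(nrow(correct))) {
    g <- correct$genome_id[i]
    if (g %in% recovered) next
    b <- blocks[blocks$scaffold_id == correct$scaffold_id[i] &
                  blocks$genome_id == g, , drop = FALSE]
    L <- glen[[g]]
    cov <- if (gcirc[[g]]) circular_union_len(b$g_start, b$g_end, L)
           else interval_union_len(b$g_start, pmin(b$g_end, L))
    if (cov / L >= params$recovery_fraction) recovered <- c(recovered, g)
  }
  list(hit = hit, recovered = recovered)
}

#' Evaluate an assembly against truth genomes
#'
#' Runs the full evaluation: filters scaffolds below the minimum length,
#' aligns them to the truth genomes (or uses supplied blocks), classifies
#' each scaffold, bins by size and summarises counts, misassembly
#' percentages, N50, correctly assembled length and genome recovery.
#'
#' @param scaffolds a `genome_set` of assembled sequences.
#' @param genomes a `genome_set` of truth genomes.
#' @param params an [eval_params()]. In fragment mode the default bins are
#'   replaced by [fragment_size_bins()] unless `size_bins` was set
#'   explicitly.
#' @param fragment_mode_length truth fragment length for fragment-library
#'   evaluations, or NULL.
#' @param blocks optional precomputed alignment blocks (e.g. from
#'   [load_alignment_coords()]); when NULL the built-in aligner runs.
#' @return a `virome_eval` object: list with `summary` (per-bin table),
#'   `stats` (named totals), `verdicts`, `blocks`.
#' @export
evaluate_assembly <- function(scaffolds, genomes, params = eval_params(),
                              fragment_mode_length = NULL, blocks = NULL) {
  if (!is.null(fragment_mode_length) && missing(params)) {
    params$size_bins <- fragment_size_bins(fragment_mode_length,
                                           params$overlength_fraction,
                                           params$min_scaffold_length)
  }
  keep <- nchar(scaffolds$sequence) >= params$min_scaffold_length
  scaffolds <- scaffolds[keep, , drop = FALSE]
  if (!nrow(scaffolds)) stop("no scaffolds pass the minimum length filter")
  if (is.null(blocks)) {
    blocks <- align_scaffolds_to_truth(scaffolds, genomes,
                                       params$min_block_identity,
                                       params$min_anchor)
  }
  lens <- nchar(scaffolds$sequence)
  verdicts <- do.call(rbind, lapply(seq_len(nrow(scaffolds)), function(i) {
    classify_scaffold(scaffolds$id[i], lens[i],
                      blocks[blocks$scaffold_id == scaffolds$id[i], ,
                             drop = FALSE],
                      params, fragment_mode_length)
  }))
  bins <- params$size_bins
  bin_idx <- findInterval(verdicts$length, bins$lo)
  summary_tab <- do.call(rbind, lapply(seq_len(nrow(bins)), function(b) {
    in_bin <- bin_idx == b
    n <- sum(in_bin)
    mis <- sum(in_bin & verdicts$status == "misassembled")
    data.frame(bin = bins$label[b], n_scaffolds = n,
               pct_misassembled = if (n) as.integer(round(100 * mis / n))
                                  else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  hr <- genomes_hit_and_recovered(verdicts, blocks, genomes, params)
  n_correct <- sum(verdicts$status == "correct")
  stats <- list(
    total_scaffolds = nrow(verdicts),
    max_scaffold_length = max(verdicts$length),
    n50 = compute_n50(verdicts$length),
    correct_count = n_correct,
    correct_pct = as.integer(round(100 * n_correct / nrow(verdicts))),
    misassembled_count = sum(verdicts$status == "misassembled"),
    correct_length_mb = round(sum(verdicts$length[verdicts$status == "correct"]) / 1e6, 1),
    genomes_hit = length(hr$hit),
    genomes_recovered = length(hr$recovered)
  )
  structure(list(summary = summary_tab, stats = stats, verdicts = verdicts,
                 blocks = blocks, params = params,
                 fragment_mode_length = fragment_mode_length),
            class = "virome_eval")
}

#' @export
print.virome_eval <- function(x, ...) {
  cat("Assembly evaluation\n")
  cat(sprintf("  Number of scaffolds (%% misassembled): %d (%d)\n",
              x$stats$total_scaffolds,
              as.integer(round(100 * x$stats$misassembled_count /
                                 x$stats$total_scaffolds))))
  for (i in seq_len(nrow(x$summary))) {
    r <- x$summary[i, ]
    cat(sprintf("    %-16s %d (%s)\n", r$bin, r$n_scaffolds,
                ifelse(is.na(r$pct_misassembled), "na", r$pct_misassembled)))
  }
  cat(sprintf("  Max scaffold length: %d\n", x$stats$max_scaffold_length))
  cat(sprintf("  N50: %d\n", x$stats$n50))
  cat(sprintf("  Scaffolds correctly mapped to genomes: %d (%d%%)\n",
              x$stats$correct_count, x$stats$correct_pct))
  cat(sprintf("  Number of misassembled scaffolds: %d\n",
              x$stats$misassembled_count))
  cat(sprintf("  Total correctly assembled length (Mb): %.1f\n",
              x$stats$correct_length_mb))
  cat(sprintf("  Genomes hit: %d\n", x$stats$genomes_hit))
  cat(sprintf("  Genomes recovered: %d\n", x$stats$genomes_recovered))
  invisible(x)
}

#' Map reads back to scaffolds and report pair concordance
#'
#' Simplified end-to-end placement: each read is anchored by exact k-mers at
#' several offsets against a scaffold k-mer index (both strands) and a
#' candidate placement is kept when gap-free verification over the full read
#' reaches `min_identity`. At most `max_alignments` placements are retained
#' per read. Reported per pair: % mapped concordantly (both mates placed on
#' one scaffold), % with >1 placement on the same scaffold, % with
#' placements on different scaffolds.
#'
#' @param pairs a `read_pairs` data.frame.
#' @param scaffolds a `genome_set`.
#' @param max_alignments maximum placements retained per read.
#' @param k anchor k-mer size.
#' @param min_identity minimum fraction of matching bases for a placement.
#' @return list with pct_concordant, pct_multi_same, pct_multi_diff and the
#'   per-read placement table.
#' @export
map_reads_back <- function(pairs, scaffolds, max_alignments = 3L, k = 31L,
                           min_identity = 0.9) {
  stopifnot(nrow(pairs) > 0, nrow(scaffolds) > 0)
  idx <- genome_kmer_index_safe(scaffolds, k)
  data.table::setkey(idx, kmer)
  place_read <- function(read) {
    rl <- nchar(read)
    if (rl < k) return(NULL)
    hits <- list()
    for (strand in c("+", "-")) {
      rs <- if (strand == "+") read else revcomp(read)
      offs <- unique(pmin(c(0L, (rl - k) %/% 2L, rl - k), rl - k))
      seeds <- data.table::data.table(
        spos = offs, kmer = substring(rs, offs + 1L, offs + k))
      cand <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (!nrow(cand)) next
      cand[, start := pos - spos]
      cand <- unique(cand[, .(genome, start)])
      for (j in seq_len(nrow(cand))) {
        g <- cand$genome[j]; st <- cand$start[j]
        gs <- scaffolds$sequence[scaffolds$id == g]
        if (st < 0 || st + rl > nchar(gs)) next
        ident <- str_matches(rs, substr(gs, st + 1L, st + rl)) / rl
        if (ident >= min_identity) {
          hits[[length(hits) + 1L]] <- data.frame(
            scaffold_id = g, start = st, strand = strand, identity = ident,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(hits)) return(NULL)
    h <- do.call(rbind, hits)
    h[order(-h$identity), , drop = FALSE][seq_len(min(nrow(h), max_alignments)), ,
                                          drop = FALSE]
  }
  n <- nrow(pairs)
  conc <- multi_same <- multi_diff <- logical(n)
  for (i in seq_len(n)) {
    p1 <- place_read(pairs$read1[i])
    p2 <- place_read(pairs$read2[i])
    placed <- rbind(p1, p2)
    if (is.null(placed) || !nrow(placed)) next
    conc[i] <- !is.null(p1) && !is.null(p2) &&
      length(intersect(p1$scaffold_id, p2$scaffold_id)) > 0
    multi_same[i] <- (!is.null(p1) && anyDuplicated(p1$scaffold_id) > 0) ||
      (!is.null(p2) && anyDuplicated(p2$scaffold_id) > 0)
    multi_diff[i] <- length(unique(placed$scaffold_id)) > 1L
  }
  list(pct_concordant = 100 * mean(conc),
       pct_multi_same = 100 * mean(multi_same),
       pct_multi_diff = 100 * mean(multi_diff))
}

# as genome_kmer_index but tolerant of short sequences (skips those < k)
genome_kmer_index_safe <- function(genomes, k) {
  keep <- nchar(genomes$sequence) >= k
  if (!any(keep)) {
    return(data.table::data.table(pos = integer(0), kmer = character(0),
                                  genome = character(0)))
  }
  genome_kmer_index(genomes[keep, , drop = FALSE], k)
}
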