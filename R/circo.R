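# Annotation of small circular Rep-encoding ssDNA (CRESS) virus contigs:
# six-frame ORF prediction that follows genes across the origin of circular
# sequences, detection of the rolling-circle replication origin (conserved
# nonanucleotide-family motif presented in the loop of an inverted-repeat
# stem), and scanning of Rep protein motifs I-III.

#' Default replication-origin motif patterns
#'
#' The nonanucleotide-family core motifs observed at circovirus-like
#' rolling-circle origins. IUPAC degenerate codes are honoured.
#'
#' @return character vector of patterns.
#' @export
default_ori_motifs <- function() {
  c("AGTATTAC", "AGTATTAT", "ATTATTAC")
}

#' Default Rep motif definitions
#'
#' Three profile sets of the conserved Rep motifs I-III: an invertebrate
#' circovirus-like profile (FTINN / HLQG / YCKKD), a degenerate profile
#' matching animal and bird circoviral Reps (II: H.Q, III: Y.KD or Y.KE;
#' motif I often unrecognisable), and a geminivirus-like profile
#' (FLTF / HLH / YCMKD). `.` matches any residue.
#'
#' @return data.frame(set, class, pattern).
#' @export
default_rep_motifs <- function() {
  data.frame(
    set = c(rep("circo-invertebrate", 3), rep("circo-degenerate", 3),
            rep("gemini-like", 3)),
    class = c("I", "II", "III", "II", "III", "III", "I", "II", "III"),
    pattern = c("FTINN", "HLQG", "YCKKD", "H.Q", "Y.KD", "Y.KE",
                "FLTF", "HLH", "YCMKD"),
    stringsAsFactors = FALSE
  )
}

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

translate_dna <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     if.fuzzy.codon = "X"))
}

#' Find open reading frames, including across a circular origin
#'
#' Scans all six frames. Circular sequences are scanned as their
#' self-concatenation with coordinates reported modulo length (so an ORF
#' may have `end < start` when it spans the origin); duplicate reports are
#' suppressed. Only maximal ORFs (the longest start for each stop) of at
#' least `min_length_nt` (start to stop inclusive) are reported.
#' Coordinates are 1-based inclusive on the forward strand; frames are
#' +1/+2/+3 and -1/-2/-3. The stop codon is excluded from the protein.
#'
#' @param sequence DNA string over A,C,G,T,N.
#' @param circular is the sequence circular?
#' @param min_length_nt minimum ORF length in nt including the stop codon;
#'   must be a positive multiple of 3.
#' @param start_codons start codon set (default ATG).
#' @param stop_codons stop codon set (default standard code).
#' @return data.frame: start, end, frame, length_nt, protein.
#' @export
find_orfs <- function(sequence, circular = FALSE, min_length_nt = 300L,
                      start_codons = "ATG",
                      stop_codons = GENETIC_CODE_STOPS) {
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains non-DNA characters")
  }
  if (min_length_nt < 3 || min_length_nt %% 3 != 0) {
    stop("min_length_nt must be a positive multiple of 3")
  }
  L <- nchar(sequence)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    scan_seq <- if (circular) paste0(s, s) else s
    SL <- nchar(scan_seq)
    codons_at <- function(off) {
      n_cod <- (SL - off) %/% 3L
      if (n_cod < 1) return(character(0))
      starts <- off + 3L * (seq_len(n_cod) - 1L) + 1L
      substring(scan_seq, starts, starts + 2L)
    }
    for (off in 0:2) {
      cods <- codons_at(off)
      if (!length(cods)) next
      is_start <- cods %in% start_codons
      is_stop <- cods %in% stop_codons
      stop_idx <- which(is_stop)
      prev_stop <- 0L
      for (si in stop_idx) {
        prev_stop_here <- prev_stop
        prev_stop <- si
        if (si - prev_stop_here < 2L) next
        starts_in <- which(is_start[(prev_stop_here + 1L):(si - 1L)])
        if (!length(starts_in)) next
        first_start <- prev_stop_here + starts_in[1]
        len_nt <- (si - first_start + 1L) * 3L
        if (len_nt < min_length_nt) next
        if (circular && len_nt > L) next
        # 0-based nt coordinates on the scanning strand
        nt_start0 <- off + (first_start - 1L) * 3L
        nt_end0 <- off + si * 3L  # exclusive, includes stop codon
        if (circular && nt_start0 >= L) next  # duplicate from second copy
        orf_seq <- substr(scan_seq, nt_start0 + 1L, nt_end0)
        if (grepl("N", orf_seq)) {
          warning("skipping ORF containing N at offset ", nt_start0 + 1L)
          next
        }
        protein <- translate_dna(substr(orf_seq, 1L, nchar(orf_seq) - 3L))
        # map to forward-strand 1-based inclusive coordinates
        if (strand == "+") {
          a <- nt_start0 + 1L
          b <- nt_end0
          frame <- paste0("+", (nt_start0 %% 3L) + 1L)
        } else {
          a <- L - (nt_end0 - 1L)
          b <- L - nt_start0
          frame <- paste0("-", (nt_start0 %% 3L) + 1L)
        }
        if (circular) {
          a <- (a - 1L) %% L + 1L
          b <- (b - 1L) %% L + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          start = a, end = b, frame = frame, length_nt = len_nt,
          protein = protein, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = character(0), length_nt = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(res$start, res$end), , drop = FALSE]
}

# IUPAC degenerate matching of a pattern on a subject; returns 0-based
# start positions
iupac_match <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                fixed = FALSE)
  BiocGenerics::start(m) - 1L
}

# count mismatches between string b and revcomp(a); equal lengths.
# fast path avoiding DNAStringSet construction in the inner search loop
COMP_MAP <- local({
  m <- integer(127)
  m[utf8ToInt("A")] <- utf8ToInt("T")
  m[utf8ToInt("C")] <- utf8ToInt("G")
  m[utf8ToInt("G")] <- utf8ToInt("C")
  m[utf8ToInt("T")] <- utf8ToInt("A")
  m[utf8ToInt("N")] <- utf8ToInt("N")
  m
})

arm_mismatches <- function(a, b) {
  sum(rev(COMP_MAP[utf8ToInt(a)]) != utf8ToInt(b))
}

#' Detect putative rolling-circle replication origins
#'
#' Finds every occurrence (both strands) of any motif pattern, then searches
#' for inverted-repeat arms flanking it: a left arm ending within `max_gap`
#' nt of the motif start and a right arm starting within `max_gap` nt of
#' the motif end, with the right arm equal to the reverse complement of the
#' left arm up to `max_arm_mismatches` mismatches. On circular sequences
#' the search wraps across the origin. The longest-arm site (fewest
#' mismatches on ties) is reported per motif occurrence. Coordinates are
#' 1-based inclusive on the forward strand; for a wrapped site they refer
#' to the position modulo sequence length.
#'
#' @param sequence DNA string.
#' @param circular is the sequence circular?
#' @param motif_patterns IUPAC motif patterns (default
#'   [default_ori_motifs()]).
#' @param arm_length_range integer c(min, max) arm length in nt.
#' @param max_arm_mismatches maximum arm mismatches (0 = perfect stem).
#' @param max_gap maximum gap between each arm and the motif.
#' @return data.frame: motif, strand, motif_start, motif_end, arm_length,
#'   arm_mismatches, left_arm_start, left_arm_end, right_arm_start,
#'   right_arm_end.
#' @export
find_ori <- function(sequence, circular = FALSE,
                     motif_patterns = default_ori_motifs(),
                     arm_length_range = c(8L, 20L),
                     max_arm_mismatches = 1L, max_gap = 10L) {
  if (!length(motif_patterns)) stop("motif_patterns must be non-empty")
  stopifnot(length(arm_length_range) == 2,
            arm_length_range[1] >= 1,
            arm_length_range[1] <= arm_length_range[2])
  L <- nchar(sequence)
  pad <- if (circular) {
    arm_length_range[2] + max_gap + max(nchar(motif_patterns))
  } else 0L
  ext <- if (circular) paste0(sequence, substr(sequence, 1L, pad)) else sequence
  sites <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") ext else revcomp(ext)
    for (pat in motif_patterns) {
      for (m0 in iupac_match(pat, subj)) {
        plen <- nchar(pat)
        best <- NULL
        for (alen in seq(arm_length_range[2], arm_length_range[1])) {
          for (g1 in 0:max_gap) {
            l_end <- m0 - g1          # exclusive, 0-based
            l_start <- l_end - alen
            if (l_start < 0) next
            left <- substr(subj, l_start + 1L, l_end)
            for (g2 in 0:max_gap) {
              r_start <- m0 + plen + g2
              r_end <- r_start + alen
              if (r_end > nchar(subj)) next
              right <- substr(subj, r_start + 1L, r_end)
              mm <- arm_mismatches(left, right)
              if (mm <= max_arm_mismatches &&
                  (is.null(best) || alen > best$alen ||
                     (alen == best$alen && mm < best$mm))) {
                best <- list(alen = alen, mm = mm,
                             l_start = l_start, l_end = l_end,
                             r_start = r_start, r_end = r_end)
              }
            }
          }
          if (!is.null(best) && best$alen == alen) break  # longest arm found
        }
        if (is.null(best)) next
        # map 0-based positions on the scanning strand back to forward
        # 1-based coordinates
        to_fwd <- function(p0, len) {
          if (strand == "+") c(p0 + 1L, p0 + len)
          else c(nchar(subj) - (p0 + len) + 1L, nchar(subj) - p0)
        }
        mo <- to_fwd(m0, plen)
        la <- to_fwd(best$l_start, best$alen)
        ra <- to_fwd(best$r_start, best$alen)
        if (strand == "-") { tmp <- la; la <- ra; ra <- tmp }
        wrap1 <- function(x) if (circular) (x - 1L) %% L + 1L else x
        sites[[length(sites) + 1L]] <- data.frame(
          motif = pat, strand = strand,
          motif_start = wrap1(mo[1]), motif_end = wrap1(mo[2]),
          arm_length = best$alen, arm_mismatches = best$mm,
          left_arm_start = wrap1(la[1]), left_arm_end = wrap1(la[2]),
          right_arm_start = wrap1(ra[1]), right_arm_end = wrap1(ra[2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(sites)) {
    return(data.frame(motif = character(0), strand = character(0),
                      motif_start = integer(0), motif_end = integer(0),
                      arm_length = integer(0), arm_mismatches = integer(0),
                      left_arm_start = integer(0), left_arm_end = integer(0),
                      right_arm_start = integer(0), right_arm_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, sites))
  # motifs in the circular pad duplicate an unpadded occurrence (the pad
  # exists so flanking arms can wrap); keep the best arm per site
  res <- res[order(-res$arm_length, res$arm_mismatches), , drop = FALSE]
  res <- res[!duplicated(res[c("motif", "strand", "motif_start")]), ,
             drop = FALSE]
  res <- res[order(res$motif_start, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a protein for Rep motifs I-III
#'
#' Matches every pattern of every motif definition set against the protein
#' (patterns are position-wildcarded: `.` matches any residue) and reports
#' all matches with their class and 1-based position.
#'
#' @param protein amino-acid string.
#' @param motif_definitions data.frame(set, class, pattern); default
#'   [default_rep_motifs()].
#' @return data.frame: set, class, pattern, position.
#' @export
scan_rep_motifs <- function(protein, motif_definitions = default_rep_motifs()) {
  empty <- data.frame(set = character(0), class = character(0),
                      pattern = character(0), position = integer(0),
                      stringsAsFactors = FALSE)
  if (!nchar(protein)) return(empty)
  hits <- list()
  for (i in seq_len(nrow(motif_definitions))) {
    pat <- motif_definitions$pattern[i]
    # overlapping matches via lookahead
    m <- gregexpr(paste0("(?=", pat, ")"), protein, perl = TRUE)[[1]]
    if (m[1] == -1) next
    hits[[length(hits) + 1L]] <- data.frame(
      set = motif_definitions$set[i],
      class = motif_definitions$class[i],
      pattern = pat, position = as.integer(m),
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  res <- do.call(rbind, hits)
  res[order(res$position, res$class), , drop = FALSE]
}
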