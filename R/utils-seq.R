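#' @importFrom stats rnorm runif median setNames
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a genome set
#'
#' A genome set is the package's container for reference replicons: a
#' data.frame with columns `id`, `sequence` and `circular`.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of DNA sequences over A,C,G,T,N.
#' @param circular logical vector (recycled) marking circular replicons.
#' @return a `genome_set` data.frame.
#' @export
genome_set <- function(id, sequence, circular = FALSE) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) stop("genome ids must be unique")
  if (length(sequence) && any(nchar(sequence) < 1L)) {
    stop("sequences must have length >= 1")
  }
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) stop("non-DNA characters in sequence(s): ", paste(id[bad], collapse = ", "))
  out <- data.frame(
    id = as.character(id),
    sequence = as.character(sequence),
    circular = rep_len(as.logical(circular), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("genome_set", "data.frame")
  out
}

#' Generate random genomes for simulations
#'
#' @param n number of genomes.
#' @param lengths integer vector (recycled) of genome lengths.
#' @param circular logical vector (recycled).
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return a `genome_set`.
#' @export
random_genomes <- function(n, lengths = 20000L, circular = FALSE, seed = 1L,
                           prefix = "g") {
  stopifnot(n >= 1)
  set.seed(seed)
  lengths <- rep_len(as.integer(lengths), n)
  seqs <- vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  genome_set(paste0(prefix, seq_len(n)), seqs, circular)
}

# substring extraction on circular sequences: 0-based start, length len,
# wrapping around the origin when needed
circ_substr <- function(seq, start0, len) {
  L <- nchar(seq)
  start0 <- start0 %% L
  if (start0 + len <= L) {
    substr(seq, start0 + 1L, start0 + len)
  } else {
    paste0(
      substr(seq, start0 + 1L, L),
      circ_substr(seq, 0L, len - (L - start0))
    )
  }
}

# all k-mer start positions (0-based) and strings of a sequence
kmerize <- function(seq, k, step = 1L) {
  L <- nchar(seq)
  if (L < k) return(data.table::data.table(pos = integer(0), kmer = character(0)))
  pos <- seq.int(0L, L - k, by = step)
  data.table::data.table(pos = pos, kmer = substring(seq, pos + 1L, pos + k))
}

# compare two equal-length strings base by base; returns number of matches
str_matches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) == utf8ToInt(b))
}

#' Read genomes or contigs from FASTA
#'
#' A `circular=true` token in a record's description line marks the replicon
#' circular.
#'
#' @param path FASTA file.
#' @return a `genome_set`.
#' @export
read_genomes_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  circ <- grepl("circular=true", nm, ignore.case = TRUE)
  id <- vapply(strsplit(nm, "\\s+"), `[[`, character(1), 1L)
  genome_set(id, as.character(ss), circ)
}

#' Write genomes or contigs to FASTA
#'
#' @param genomes a `genome_set` (or any data.frame with id/sequence and
#'   optionally circular columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(genomes, path) {
  ss <- Biostrings::DNAStringSet(genomes$sequence)
  circ <- if (!is.null(genomes$circular)) genomes$circular else FALSE
  names(ss) <- ifelse(rep_len(circ, nrow(genomes)),
                      paste0(genomes$id, " circular=true"), genomes$id)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write simulated read pairs as a pair of FASTQ files
#'
#' Files are written Phred+33; `path_prefix` receives `_1.fastq` and
#' `_2.fastq` suffixes.
#'
#' @param pairs a `read_pairs` object from [simulate_read_pairs()].
#' @param path_prefix output prefix.
#' @return character vector of the two file paths, invisibly.
#' @export
write_read_pairs_fastq <- function(pairs, path_prefix) {
  out <- paste0(path_prefix, c("_1.fastq", "_2.fastq"))
  w <- function(seqs, quals, ids, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- ids
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  w(pairs$read1, pairs$qual1, pairs$pair_id, out[1])
  w(pairs$read2, pairs$qual2, pairs$pair_id, out[2])
  invisible(out)
}
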