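#' Sample a skewed (lognormal) abundance profile
#'
#' Environmental viromes show strongly skewed species abundances; a lognormal
#' profile is the standard stand-in when the true composition is unknown.
#' Weights are per-genome copy numbers normalised to sum to one.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param sigma lognormal shape parameter on the log scale; 0 gives a uniform
#'   profile.
#' @param seed integer seed.
#' @param ids optional genome ids (default `g1..gN`).
#' @return named numeric vector of relative abundances summing to 1.
#' @export
sample_abundance_profile <- function(n_genomes, sigma = 1.5, seed = 1L,
                                     ids = NULL) {
  if (n_genomes < 1) stop("n_genomes must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  w <- exp(rnorm(n_genomes, mean = 0, sd = sigma))
  w <- w / sum(w)
  if (is.null(ids)) ids <- paste0("g", seq_len(n_genomes))
  stopifnot(length(ids) == n_genomes)
  setNames(w, ids)
}

#' Fragment genomes into fixed-length non-overlapping pieces
#'
#' Cuts each genome into consecutive windows of exactly `fragment_length`
#' starting at position 1; a trailing window shorter than `fragment_length`
#' is discarded. With `keep_every_second`, only even-index (0-based, per
#' genome) windows are retained — emulating libraries built from alternating
#' genome pieces so that neighbouring fragments never overlap or abut in the
#' retained set.
#'
#' @param genomes a `genome_set`.
#' @param fragment_length window size in nt (>= 1).
#' @param keep_every_second drop every second window per genome.
#' @return a `fragment_library`: list with `fragments` (a linear
#'   `genome_set`) and `parent_map` (data.frame fragment_id, parent_id,
#'   start, end; 0-based half-open parent coordinates).
#' @export
fragment_genomes <- function(genomes, fragment_length = 2000L,
                             keep_every_second = FALSE) {
  if (fragment_length < 1) stop("fragment_length must be >= 1")
  rows <- lapply(seq_len(nrow(genomes)), function(i) {
    L <- nchar(genomes$sequence[i])
    n_win <- L %/% fragment_length
    if (n_win == 0L) return(NULL)
    idx <- seq_len(n_win) - 1L
    if (keep_every_second) idx <- idx[idx %% 2L == 0L]
    if (!length(idx)) return(NULL)
    start <- idx * fragment_length
    data.frame(
      fragment_id = sprintf("%s_frag%d", genomes$id[i], idx + 1L),
      parent_id = genomes$id[i],
      start = start,
      end = start + fragment_length,
      sequence = substring(genomes$sequence[i], start + 1L,
                           start + fragment_length),
      stringsAsFactors = FALSE
    )
  })
  pm <- do.call(rbind, rows)
  if (is.null(pm)) {
    pm <- data.frame(fragment_id = character(0), parent_id = character(0),
                     start = integer(0), end = integer(0),
                     sequence = character(0), stringsAsFactors = FALSE)
  }
  frags <- genome_set(pm$fragment_id, pm$sequence, circular = FALSE)
  structure(list(fragments = frags,
                 parent_map = pm[c("fragment_id", "parent_id", "start", "end")]),
            class = "fragment_library")
}

#' Spike selected genomes into a profile at high abundance
#'
#' Emulates datasets in which a few small circular genomes reach excessive
#' read coverage (e.g. through rolling-circle amplification bias): each spike
#' genome receives `spike_fold` times the median base weight, then the whole
#' profile is renormalised.
#'
#' @param base named numeric abundance profile.
#' @param spike_ids ids to spike (added if absent from `base`).
#' @param spike_fold multiple of the median base weight (> 0); default 1000.
#' @return named numeric profile summing to 1.
#' @export
make_spiked_profile <- function(base, spike_ids, spike_fold = 1000) {
  if (!length(base)) stop("base profile is empty")
  if (spike_fold <= 0) stop("spike_fold must be > 0")
  if (!length(spike_ids)) return(base / sum(base))
  w <- base
  spike_w <- spike_fold * median(base)
  w[spike_ids] <- spike_w
  w / sum(w)
}

#' Simulation settings for paired-end read generation
#'
#' Defaults follow common 300 nt virome sequencing runs: 450 nt inserts with
#' 10% standard deviation and a ~1% substitution rate (0.9% is typical for
#' 80 nt reads; pass `substitution_rate = 0.009` with `read_length = 80`).
#'
#' @param n_pairs number of read pairs (>= 1).
#' @param read_length read length in nt.
#' @param insert_mean mean insert size in nt (>= read_length).
#' @param insert_sd_fraction insert-size sd as a fraction of the mean.
#' @param substitution_rate mean per-base substitution probability in [0,1).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pairs, read_length = 300L, insert_mean = 450L,
                       insert_sd_fraction = 0.10,
                       substitution_rate = if (read_length == 80L) 0.009 else 0.01,
                       seed = 1L) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (substitution_rate < 0 || substitution_rate >= 1) {
    stop("substitution_rate must be in [0, 1)")
  }
  if (insert_mean < read_length) stop("insert_mean must be >= read_length")
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean,
                 insert_sd_fraction = insert_sd_fraction,
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# per-base substitution probability ramp: linear from 0.5x to 1.5x the target
# rate along the read, so the mean equals the target rate
error_ramp <- function(read_length, rate) {
  if (read_length == 1L) return(rate)
  rate * seq(0.5, 1.5, length.out = read_length)
}

# apply substitutions to a character vector of equal-length reads;
# returns list(seq = mutated reads, qual = Phred+33 quality strings)
mutate_reads <- function(reads, rate) {
  n <- length(reads)
  rl <- nchar(reads[1])
  p <- error_ramp(rl, rate)
  q_int <- pmin(41L, as.integer(round(-10 * log10(pmax(p, 1e-4)))))
  qual <- paste(intToUtf8(q_int + 33L, multiple = TRUE), collapse = "")
  if (rate == 0) {
    return(list(seq = reads, qual = rep(qual, n)))
  }
  m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE), nrow = rl)
  hit <- runif(length(m)) < rep(p, times = n)
  if (any(hit)) {
    # substitute with one of the three other bases, uniformly
    orig <- m[hit]
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    idx <- (match(orig, DNA_BASES) - 1L + shift) %% 4L + 1L
    idx[is.na(idx)] <- 1L  # N bases become A on substitution
    m[hit] <- DNA_BASES[idx]
  }
  list(seq = apply_paste(m), qual = rep(qual, n))
}

apply_paste <- function(m) {
  # fast column-wise paste of a character matrix
  do.call(paste0, split(m, row(m)))
}

#' Simulate paired-end virome reads
#'
#' Templates are chosen per pair with probability proportional to
#' `profile[id] * nchar(sequence)` (per-copy abundance semantics: the profile
#' gives genome copy numbers, so longer genomes shed proportionally more
#' reads). Insert lengths are normal (mean `insert_mean`, sd
#' `insert_sd_fraction * insert_mean`), rounded and clamped to
#' `[read_length, template length]`; fragment start is uniform, with
#' wrap-around permitted on circular templates. Read 2 is the reverse
#' complement of the insert's far end. Substitution errors follow a linear
#' position ramp whose mean equals `substitution_rate`; qualities encode the
#' per-base error probability (Phred+33).
#'
#' @param templates a `genome_set`.
#' @param profile named abundance profile; every name must be a template id.
#' @param config a [sim_config()].
#' @return a `read_pairs` data.frame: pair_id, read1, qual1, read2, qual2,
#'   template, start, end, strand. `start`/`end` are 0-based half-open on the
#'   template (end may exceed template length for wrap-around fragments).
#' @export
simulate_read_pairs <- function(templates, profile, config) {
  missing_t <- setdiff(names(profile), templates$id)
  if (length(missing_t)) {
    stop("profile references missing template(s): ",
         paste(missing_t, collapse = ", "))
  }
  rl <- config$read_length
  tpl <- templates[match(names(profile), templates$id), ]
  lens <- nchar(tpl$sequence)
  usable <- tpl$circular | lens >= rl
  if (!all(usable)) {
    warning("excluding template(s) shorter than read_length: ",
            paste(tpl$id[!usable], collapse = ", "))
    tpl <- tpl[usable, ]
    profile <- profile[usable]
    lens <- lens[usable]
    if (!nrow(tpl)) stop("no usable templates remain")
  }
  set.seed(config$seed)
  n <- config$n_pairs
  w <- profile * lens
  ti <- sample.int(nrow(tpl), n, replace = TRUE, prob = w / sum(w))
  ins <- as.integer(round(rnorm(n, config$insert_mean,
                                config$insert_sd_fraction * config$insert_mean)))
  L <- lens[ti]
  ins <- pmax(rl, pmin(ins, L))
  circ <- tpl$circular[ti]
  # uniform start: linear templates must fit the insert; circular wrap
  start <- ifelse(circ,
                  floor(runif(n) * L),
                  floor(runif(n) * (L - ins + 1)))
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  frag <- vapply(seq_len(n), function(i) {
    circ_substr(tpl$sequence[ti[i]], start[i], ins[i])
  }, character(1))
  fwd <- frag
  neg <- strand == "-"
  fwd[neg] <- revcomp(frag[neg])
  r1 <- substr(fwd, 1L, rl)
  r2 <- revcomp(substr(fwd, nchar(fwd) - rl + 1L, nchar(fwd)))
  m1 <- mutate_reads(r1, config$substitution_rate)
  m2 <- mutate_reads(r2, config$substitution_rate)
  out <- data.frame(
    pair_id = sprintf("pair_%d", seq_len(n)),
    read1 = m1$seq, qual1 = m1$qual,
    read2 = m2$seq, qual2 = m2$qual,
    template = tpl$id[ti],
    start = start, end = start + ins,
    strand = strand,
    stringsAsFactors = FALSE
  )
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Plan a mock assembly with planted, labelled artifacts
#'
#' Each artifact is one of:
#' \describe{
#'   \item{faithful}{an exact copy of `genome[start, end)`.}
#'   \item{chimera}{concatenation of intervals from two genomes.}
#'   \item{duplicate_cluster}{`n` copies of a genome interval, each optionally
#'     truncated (random retained fraction >= `1 - max_truncation`) and
#'     point-mutated at `mutation_rate`.}
#'   \item{truncation}{a partial copy (alias for faithful with a sub-interval;
#'     labelled `truncation`).}
#' }
#'
#' @param faithful data.frame(genome, start, end) or NULL. Coordinates are
#'   0-based half-open; NA start/end means the whole genome.
#' @param chimera data.frame(genome_a, start_a, end_a, genome_b, start_b,
#'   end_b) or NULL.
#' @param duplicate_cluster data.frame(genome, n, max_truncation,
#'   mutation_rate) or NULL.
#' @param truncation data.frame(genome, start, end) or NULL.
#' @param seed integer seed for the stochastic artifacts.
#' @return a `mock_plan` list.
#' @export
mock_assembly_plan <- function(faithful = NULL, chimera = NULL,
                               duplicate_cluster = NULL, truncation = NULL,
                               seed = 1L) {
  structure(list(faithful = faithful, chimera = chimera,
                 duplicate_cluster = duplicate_cluster,
                 truncation = truncation, seed = as.integer(seed)),
            class = "mock_plan")
}

#' Generate a mock assembly with planted errors
#'
#' Emits one scaffold per planted artifact (a duplicate cluster emits its `n`
#' copies) together with a truth table labelling each scaffold, for testing
#' misassembly classifiers and duplicate-network detectors against known
#' ground truth.
#'
#' @param genomes a `genome_set`.
#' @param plan a [mock_assembly_plan()].
#' @return list with `scaffolds` (a `genome_set`) and `truth` (data.frame
#'   scaffold_id, label, provenance); labels are faithful, chimeric,
#'   duplicate-member or truncation.
#' @export
generate_mock_assembly <- function(genomes, plan) {
  set.seed(plan$seed)
  gseq <- setNames(genomes$sequence, genomes$id)
  need <- function(g) {
    if (!g %in% names(gseq)) stop("plan references unknown genome: ", g)
    gseq[[g]]
  }
  cut0 <- function(s, a, b) {
    if (is.na(a)) a <- 0L
    if (is.na(b)) b <- nchar(s)
    if (a < 0 || b > nchar(s) || a >= b) stop("interval outside genome bounds")
    substr(s, a + 1L, b)
  }
  ids <- character(0); seqs <- character(0)
  labels <- character(0); prov <- character(0)
  add <- function(id, sq, lab, pv) {
    ids <<- c(ids, id); seqs <<- c(seqs, sq)
    labels <<- c(labels, lab); prov <<- c(prov, pv)
  }
  for (i in seq_len(NROW(plan$faithful))) {
    r <- plan$faithful[i, ]
    s <- cut0(need(r$genome), r$start, r$end)
    add(sprintf("faithful_%d", i), s, "faithful",
        sprintf("%s[%s,%s)", r$genome, r$start, r$end))
  }
  for (i in seq_len(NROW(plan$truncation))) {
    r <- plan$truncation[i, ]
    s <- cut0(need(r$genome), r$start, r$end)
    add(sprintf("trunc_%d", i), s, "truncation",
        sprintf("%s[%s,%s)", r$genome, r$start, r$end))
  }
  for (i in seq_len(NROW(plan$chimera))) {
    r <- plan$chimera[i, ]
    s <- paste0(cut0(need(r$genome_a), r$start_a, r$end_a),
                cut0(need(r$genome_b), r$start_b, r$end_b))
    add(sprintf("chimera_%d", i), s, "chimeric",
        sprintf("%s+%s", r$genome_a, r$genome_b))
  }
  for (i in seq_len(NROW(plan$duplicate_cluster))) {
    r <- plan$duplicate_cluster[i, ]
    if (r$n < 2) stop("duplicate_cluster requires n >= 2")
    base <- need(r$genome)
    L <- nchar(base)
    for (j in seq_len(r$n)) {
      keep <- if (r$max_truncation > 0) {
        as.integer(round(L * runif(1, 1 - r$max_truncation, 1)))
      } else L
      s <- substr(base, 1L, max(keep, 1L))
      if (r$mutation_rate > 0) {
        s <- mutate_reads(s, r$mutation_rate)$seq
      }
      add(sprintf("dup%d_copy%d", i, j), s, "duplicate-member",
          sprintf("cluster%d:%s", i, r$genome))
    }
  }
  list(
    scaffolds = genome_set(ids, seqs, circular = FALSE),
    truth = data.frame(scaffold_id = ids, label = labels, provenance = prov,
                       stringsAsFactors = FALSE)
  )
}

#' Remove exact duplicate read pairs
#'
#' Retains the first occurrence of each exact (read1, read2) sequence pair,
#' preserving order, and reports the number removed.
#'
#' @param pairs a `read_pairs` data.frame (needs read1 and read2 columns).
#' @return list with `pairs` (deduplicated) and `n_removed`.
#' @export
remove_duplicate_reads <- function(pairs) {
  key <- paste(pairs$read1, pairs$read2, sep = "\r")
  keep <- !duplicated(key)
  list(pairs = pairs[keep, , drop = FALSE], n_removed = sum(!keep))
}
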