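# Score-based taxonomic kingdom assignment of predicted proteins.
#
# Each protein carries similarity hits from up to three databases: a viral
# RefSeq subset (the screening annotation), NCBI-nr and RefSeq-P. The final
# kingdom call compares the top-scoring hit per source and applies, in
# order: (a) the viral-subset hit scores strictly highest; (d) a protein
# domain annotation is itself viral; (b) the best nr/RefSeq-P hit is
# taxonomically viral at e-value < 1e-4 and bit score >= 45; (c) its
# subject title contains a viral keyword under the same thresholds;
# putative-Viruses when viral evidence exists but the e-value threshold
# fails; otherwise the cellular kingdom of the best hit, or unclassified.

KINGDOMS <- c("Archaea", "Bacteria", "Eukaryota")

default_stoplist <- function() {
  c("protein", "hypothetical", "putative", "uncharacterized", "predicted",
    "probable", "unnamed", "product", "partial", "conserved", "domain",
    "family", "gene", "orf", "the", "and", "with", "like")
}

#' Make a protein hit record table
#'
#' @param protein_id character vector.
#' @param source one of "viral-subset", "nr", "refseq-p" per hit.
#' @param subject_title subject description line.
#' @param lineage taxonomy path strings, `;`-separated (may be empty).
#' @param bit_score positive numeric.
#' @param evalue non-negative numeric.
#' @return data.frame of class `protein_hits`.
#' @export
protein_hits <- function(protein_id, source, subject_title = "",
                         lineage = "", bit_score, evalue) {
  source <- match.arg(source, c("viral-subset", "nr", "refseq-p"),
                      several.ok = TRUE)
  stopifnot(all(bit_score > 0), all(evalue >= 0))
  n <- length(protein_id)
  out <- data.frame(protein_id = protein_id,
                    source = rep_len(source, n),
                    subject_title = rep_len(subject_title, n),
                    lineage = rep_len(lineage, n),
                    bit_score = rep_len(bit_score, n),
                    evalue = rep_len(evalue, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_hits", "data.frame")
  out
}

#' Viral screening call for a viral-subset hit
#'
#' A protein is annotated viral by the screening database iff its bit score
#' against the viral RefSeq subset is strictly above 50.
#'
#' @param bit_score bit score of the viral-subset hit.
#' @param source hit source; must be "viral-subset".
#' @return logical.
#' @export
metavir_viral_call <- function(bit_score, source = "viral-subset") {
  if (!identical(source, "viral-subset")) {
    stop("metavir_viral_call applies to viral-subset hits only")
  }
  bit_score > 50
}

#' Build a viral keyword dictionary from winning annotations
#'
#' Tokenises subject titles of proteins whose viral-subset annotation won
#' the score comparison: lower-cases, strips punctuation, drops stop-words
#' and tokens shorter than 3 characters. Hyphen- or space-joined word pairs
#' occurring in at least two titles are additionally kept as phrases.
#'
#' @param winning_titles character vector of subject titles.
#' @param stoplist lower-case tokens to exclude.
#' @return a `keyword_dict` list with `keywords` (character set) and
#'   `provenance` (the input titles).
#' @export
build_keyword_dictionary <- function(winning_titles,
                                     stoplist = default_stoplist()) {
  titles <- unique(tolower(winning_titles))
  toks <- lapply(titles, function(t) {
    t2 <- gsub("[^a-z0-9 -]", " ", t)
    words <- unlist(strsplit(gsub("-", " ", t2), "\\s+"))
    words[nchar(words) >= 3 & !words %in% stoplist]
  })
  keywords <- unique(unlist(toks))
  # two-word phrases recurring across titles
  phrases <- unlist(lapply(titles, function(t) {
    t2 <- gsub("[^a-z0-9 -]", " ", t)
    words <- unlist(strsplit(gsub("-", " ", t2), "\\s+"))
    words <- words[nzchar(words)]
    if (length(words) < 2) return(character(0))
    unique(paste(words[-length(words)], words[-1]))
  }))
  phrase_counts <- table(phrases)
  keep_phrases <- names(phrase_counts)[phrase_counts >= 2]
  if (length(keep_phrases)) {
    keep_phrases <- keep_phrases[!vapply(strsplit(keep_phrases, " "),
                                         function(w) all(w %in% stoplist),
                                         logical(1))]
  } else {
    keep_phrases <- character(0)
  }
  structure(list(keywords = sort(unique(c(keywords, keep_phrases))),
                 provenance = winning_titles),
            class = "keyword_dict")
}

# whole-token, case-insensitive keyword match against a title
title_has_keyword <- function(title, dict) {
  if (!length(dict$keywords)) return(FALSE)
  t <- tolower(title)
  words <- unlist(strsplit(gsub("[^a-z0-9 -]", " ", gsub("-", " ", t)), "\\s+"))
  words <- words[nzchar(words)]
  if (any(words %in% dict$keywords)) return(TRUE)
  if (length(words) >= 2) {
    bi <- paste(words[-length(words)], words[-1])
    if (any(bi %in% dict$keywords)) return(TRUE)
  }
  FALSE
}

lineage_kingdom <- function(lineage) {
  parts <- trimws(unlist(strsplit(lineage, ";")))
  if ("Viruses" %in% parts) return("Viruses")
  hit <- intersect(KINGDOMS, parts)
  if (length(hit)) hit[1] else NA_character_
}

#' Assign the final taxonomic kingdom of a protein
#'
#' Applies the score-based decision rules (see the package vignette): the
#' top-scoring hit per source is selected and the first rule that fires, in
#' order a, d, b, c, putative, cellular, decides the class.
#'
#' @param hits `protein_hits` rows for one protein (may be empty).
#' @param domains data.frame(protein_id, accession, description, viral_flag)
#'   rows for this protein, or NULL.
#' @param keywords a `keyword_dict` (may be empty).
#' @param max_evalue e-value threshold for confident calls (default 1e-4).
#' @param min_bit minimum bit score for rules b and c (default 45).
#' @return one-row data.frame: class, rule, source, bit_score, evalue.
#' @export
assign_kingdom <- function(hits, domains = NULL,
                           keywords = build_keyword_dictionary(character(0)),
                           max_evalue = 1e-4, min_bit = 45) {
  call_row <- function(class, rule, src = NA_character_, bit = NA_real_,
                       ev = NA_real_) {
    data.frame(class = class, rule = rule, source = src, bit_score = bit,
               evalue = ev, stringsAsFactors = FALSE)
  }
  viral_domain <- !is.null(domains) && nrow(domains) > 0 &&
    any(domains$viral_flag)
  if (is.null(hits) || !nrow(hits)) {
    hits <- data.frame(protein_id = character(0), source = character(0),
                       subject_title = character(0), lineage = character(0),
                       bit_score = numeric(0), evalue = numeric(0),
                       stringsAsFactors = FALSE)
  }
  hits <- hits[order(-hits$bit_score, hits$evalue, hits$source), ,
               drop = FALSE]
  top <- hits[!duplicated(hits$source), , drop = FALSE]
  vs <- top[top$source == "viral-subset", , drop = FALSE]
  db <- top[top$source != "viral-subset", , drop = FALSE]
  best_db <- if (nrow(db)) db[which.max(db$bit_score), , drop = FALSE] else NULL
  # rule a: the viral-subset annotation scores strictly highest
  if (nrow(vs) &&
      (is.null(best_db) || vs$bit_score > best_db$bit_score)) {
    return(call_row("Viruses", "a", "viral-subset", vs$bit_score, vs$evalue))
  }
  # rule d: a domain annotation is itself viral
  if (viral_domain) {
    return(call_row("Viruses", "d", "domain"))
  }
  if (!is.null(best_db)) {
    viral_lineage <- identical(lineage_kingdom(best_db$lineage), "Viruses")
    viral_keyword <- title_has_keyword(best_db$subject_title, keywords)
    confident <- best_db$evalue < max_evalue & best_db$bit_score >= min_bit
    if (viral_lineage && confident) {
      return(call_row("Viruses", "b", best_db$source, best_db$bit_score,
                      best_db$evalue))
    }
    if (viral_keyword && confident) {
      return(call_row("Viruses", "c", best_db$source, best_db$bit_score,
                      best_db$evalue))
    }
    if (viral_lineage || viral_keyword) {
      return(call_row("putative-Viruses", "putative", best_db$source,
                      best_db$bit_score, best_db$evalue))
    }
    kg <- lineage_kingdom(best_db$lineage)
    if (!is.na(kg) && best_db$evalue < max_evalue) {
      return(call_row(kg, "cellular", best_db$source, best_db$bit_score,
                      best_db$evalue))
    }
  }
  call_row("unclassified", "none")
}

#' Kingdom calls for a full hit table
#'
#' @param hits a `protein_hits` table covering many proteins.
#' @param domains optional domain table (protein_id, accession,
#'   description, viral_flag).
#' @param keywords a `keyword_dict`.
#' @param ... passed to [assign_kingdom()].
#' @return data.frame: protein_id, class, rule, source, bit_score, evalue.
#' @export
assign_kingdoms <- function(hits, domains = NULL,
                            keywords = build_keyword_dictionary(character(0)),
                            ...) {
  ids <- unique(c(hits$protein_id,
                  if (!is.null(domains)) domains$protein_id))
  rows <- lapply(ids, function(p) {
    h <- hits[hits$protein_id == p, , drop = FALSE]
    d <- if (!is.null(domains)) domains[domains$protein_id == p, ,
                                        drop = FALSE]
    cbind(data.frame(protein_id = p, stringsAsFactors = FALSE),
          assign_kingdom(h, d, keywords, ...))
  })
  do.call(rbind, rows)
}

#' Construct a taxonomy tree
#'
#' @param id integer node ids.
#' @param parent integer parent ids; the root is self-parented.
#' @param name optional node names.
#' @param rank optional node ranks.
#' @return a `taxonomy_tree` list with a parent lookup.
#' @export
taxonomy_tree <- function(id, parent, name = as.character(id),
                          rank = NA_character_) {
  stopifnot(length(id) == length(parent))
  parent_of <- setNames(as.integer(parent), as.character(id))
  roots <- id[id == parent]
  if (length(roots) != 1L) stop("taxonomy must have exactly one self-parented root")
  # verify every node reaches the root (acyclic)
  for (n in id) {
    seen <- integer(0)
    cur <- n
    while (cur != parent_of[[as.character(cur)]]) {
      if (cur %in% seen) stop("cycle detected at node ", n)
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
      if (is.na(cur)) stop("node ", n, " has a parent outside the tree")
    }
  }
  structure(list(parent_of = parent_of, root = as.integer(roots),
                 name = setNames(rep_len(name, length(id)), as.character(id)),
                 rank = setNames(rep_len(rank, length(id)), as.character(id))),
            class = "taxonomy_tree")
}

#' Read a taxonomy tree from a nodes-dump or tabular file
#'
#' Accepts either the NCBI `nodes.dmp` dialect (fields separated by
#' `\t|\t`) or a plain 2-3 column TSV (id, parent id, optional rank).
#'
#' @param path file path.
#' @return a `taxonomy_tree`.
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (any(grepl("\\|", lines[1]))) {
    parts <- strsplit(lines, "\t\\|\t?")
    id <- as.integer(vapply(parts, `[[`, character(1), 1))
    parent <- as.integer(vapply(parts, `[[`, character(1), 2))
    rank <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else NA_character_,
                   character(1))
  } else {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    id <- as.integer(tab[[1]])
    parent <- as.integer(tab[[2]])
    rank <- if (ncol(tab) >= 3) as.character(tab[[3]]) else NA_character_
  }
  taxonomy_tree(id, parent, rank = rank)
}

# ancestor path from a node up to the root (inclusive)
ancestors_of <- function(taxonomy, node) {
  path <- integer(0)
  cur <- as.integer(node)
  repeat {
    path <- c(path, cur)
    p <- taxonomy$parent_of[[as.character(cur)]]
    if (is.null(p) || is.na(p) || p == cur) break
    cur <- p
  }
  path
}

#' MEGAN-style lowest common ancestor assignment
#'
#' Hits are filtered to `bit_score >= min_score` and `evalue <= max_evalue`;
#' of the survivors only those within `top_percent` of the best bit score
#' are retained, and the LCA of their taxa is returned (`lca_percent = 100`:
#' the ancestor of all retained taxa).
#'
#' @param taxa integer taxon ids, one per hit.
#' @param bit_score numeric bit scores.
#' @param evalue numeric e-values.
#' @param taxonomy a `taxonomy_tree`.
#' @param min_score minimum bit score (default 45).
#' @param max_evalue maximum e-value (default 1e-4).
#' @param top_percent retain hits with bit >= (1 - top_percent/100) * best
#'   (default 10).
#' @param min_support minimum number of surviving hits (default 1).
#' @return the LCA taxon id, or NA if no hits survive.
#' @export
lca_assign <- function(taxa, bit_score, evalue, taxonomy,
                       min_score = 45, max_evalue = 1e-4,
                       top_percent = 10, min_support = 1) {
  stopifnot(length(taxa) == length(bit_score),
            length(taxa) == length(evalue))
  known <- as.character(taxa) %in% names(taxonomy$parent_of)
  if (any(!known)) {
    warning("skipping hit(s) with unresolvable taxa: ",
            paste(unique(taxa[!known]), collapse = ", "))
  }
  keep <- known & bit_score >= min_score & evalue <= max_evalue
  if (sum(keep) < min_support || !any(keep)) return(NA_integer_)
  cutoff <- (1 - top_percent / 100) * max(bit_score[keep])
  keep <- keep & bit_score >= cutoff
  nodes <- unique(taxa[keep])
  paths <- lapply(nodes, function(n) ancestors_of(taxonomy, n))
  common <- Reduce(intersect, paths)
  if (!length(common)) return(NA_integer_)
  # the deepest common ancestor is the first element of any root-ward path
  # that is common to all
  paths[[1]][match(TRUE, paths[[1]] %in% common)]
}

#' Collate protein kingdom calls by contig
#'
#' @param calls data.frame with protein_id, contig_id, class.
#' @param nt_hits optional data.frame(contig_id, nt_kingdom) recording the
#'   kingdom suggested by nucleotide-level hits, for concordance reporting.
#' @param all_contig_ids optional universe of contigs (contigs without
#'   proteins get zero-count rows).
#' @return data.frame per contig: counts per class, majority class (ties ->
#'   unclassified), viral_contig flag (>= 1 confirmed Viruses protein),
#'   nt_kingdom.
#' @export
collate_contig_taxonomy <- function(calls, nt_hits = NULL,
                                    all_contig_ids = NULL) {
  classes <- c("Viruses", "putative-Viruses", KINGDOMS, "unclassified")
  contigs <- unique(c(calls$contig_id, all_contig_ids))
  rows <- lapply(contigs, function(cid) {
    cc <- calls$class[calls$contig_id == cid]
    counts <- vapply(classes, function(k) sum(cc == k), integer(1))
    majority <- if (!length(cc)) "unclassified" else {
      mx <- max(counts)
      winners <- classes[counts == mx]
      if (length(winners) == 1L) winners else "unclassified"
    }
    out <- data.frame(contig_id = cid, stringsAsFactors = FALSE)
    for (k in classes) out[[gsub("-", "_", paste0("n_", k))]] <- counts[[k]]
    out$majority_class <- majority
    out$viral_contig <- counts[["Viruses"]] >= 1L
    out$nt_kingdom <- if (!is.null(nt_hits) && cid %in% nt_hits$contig_id) {
      nt_hits$nt_kingdom[match(cid, nt_hits$contig_id)]
    } else NA_character_
    out
  })
  do.call(rbind, rows)
}

#' Cellular contamination fraction of a read set
#'
#' Percentage of distinct reads with at least one hit (e.g. to an rRNA
#' reference) at or above a bit-score threshold, reported to two decimals.
#'
#' @param read_hits data.frame(read_id, bit_score).
#' @param total_reads total number of reads screened (>= 1).
#' @param min_bitscore minimum bit score (default 80).
#' @return percentage (numeric, rounded to 2 decimals).
#' @export
contamination_fraction <- function(read_hits, total_reads, min_bitscore = 80) {
  if (total_reads < 1) stop("total_reads must be >= 1")
  if (is.null(read_hits) || !nrow(read_hits)) return(0)
  n <- length(unique(read_hits$read_id[read_hits$bit_score >= min_bitscore]))
  round(100 * n / total_reads, 2)
}
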