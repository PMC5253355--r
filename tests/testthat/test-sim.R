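test_that("abundance profiles normalise and respect dispersion", {
  expect_equal(sample_abundance_profile(1, sigma = 1, seed = 7),
               c(g1 = 1.0))
  expect_equal(unname(sample_abundance_profile(5, sigma = 0, seed = 3)),
               rep(0.2, 5))
  p <- sample_abundance_profile(100, sigma = 1.5, seed = 1)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_error(sample_abundance_profile(0), "n_genomes")
  # deterministic given seed
  expect_identical(p, sample_abundance_profile(100, sigma = 1.5, seed = 1))
})

test_that("fragmentation follows the window arithmetic oracle", {
  g <- genome_set("g1", rand_dna(5000, seed = 1))
  fl <- fragment_genomes(g, 2000, keep_every_second = FALSE)
  expect_equal(nrow(fl$fragments), 2L)
  expect_equal(fl$parent_map$start, c(0L, 2000L))
  expect_equal(fl$parent_map$end, c(2000L, 4000L))
  expect_equal(fl$fragments$sequence[1], substr(g$sequence, 1, 2000))

  fl2 <- fragment_genomes(g, 2000, keep_every_second = TRUE)
  expect_equal(nrow(fl2$fragments), 1L)
  expect_equal(fl2$parent_map$start, 0L)

  short <- genome_set("s", rand_dna(1999, seed = 2))
  expect_equal(nrow(fragment_genomes(short, 2000)$fragments), 0L)

  # property: counts match the brute-force enumerator across random lengths
  set.seed(42)
  for (i in 1:25) {
    L <- sample(100:12000, 1)
    f <- sample(c(250, 500, 2000), 1)
    kes <- sample(c(TRUE, FALSE), 1)
    gi <- genome_set("x", strrep("A", L))
    expect_equal(nrow(fragment_genomes(gi, f, kes)$fragments),
                 oracle_fragment_count(L, f, kes),
                 info = sprintf("L=%d f=%d kes=%s", L, f, kes))
  }
})

test_that("fragment intervals are non-overlapping and length-exact", {
  g <- random_genomes(3, c(7100, 4000, 1900), seed = 5)
  fl <- fragment_genomes(g, 2000)
  expect_true(all(nchar(fl$fragments$sequence) == 2000))
  by_parent <- split(fl$parent_map, fl$parent_map$parent_id)
  for (pm in by_parent) {
    pm <- pm[order(pm$start), ]
    expect_true(all(pm$start[-1] >= pm$end[-nrow(pm)]))
  }
})

test_that("spiked profiles follow the renormalisation arithmetic", {
  base <- c(a = 0.5, b = 0.5)
  sp <- make_spiked_profile(base, "c", spike_fold = 2)
  expect_equal(sp, c(a = 0.25, b = 0.25, c = 0.5))
  # monotone in fold
  f1 <- make_spiked_profile(base, "c", spike_fold = 10)["c"]
  f2 <- make_spiked_profile(base, "c", spike_fold = 100)["c"]
  expect_lt(f1, f2)
  # no spikes: identity
  expect_equal(make_spiked_profile(base, character(0), 5), base)
  expect_error(make_spiked_profile(numeric(0), "c"), "empty")
})

test_that("read pairs honour count, insert model and error model", {
  tpl <- random_genomes(1, 100000, seed = 9, prefix = "t")
  cfg <- sim_config(10000, read_length = 300, seed = 1)
  rp <- simulate_read_pairs(tpl, c(t1 = 1), cfg)
  expect_equal(nrow(rp), 10000L)
  expect_true(all(rp$template == "t1"))
  expect_true(all(nchar(rp$read1) == 300 & nchar(rp$read2) == 300))
  # mean insert within 3 standard errors of 450 (sd 45)
  ins <- rp$end - rp$start
  se <- sd(ins) / sqrt(length(ins))
  expect_lt(abs(mean(ins) - 450), 3 * se + 1e-9)
  # substitution rate within 3 binomial SE of 1%
  truth1 <- vapply(seq_len(500), function(i) {
    frag <- substr(tpl$sequence, rp$start[i] + 1, rp$end[i])
    if (rp$strand[i] == "-") frag <- revcomp(frag)
    substr(frag, 1, 300)
  }, character(1))
  mm <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
               truth1, rp$read1[1:500])
  n_bases <- 500 * 300
  rate <- sum(mm) / n_bases
  se_r <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(rate - 0.01), 3 * se_r)
})

test_that("zero-error reads are exact template substrings", {
  tpl <- random_genomes(2, c(3000, 2000), seed = 3)
  cfg <- sim_config(100, read_length = 80, substitution_rate = 0, seed = 2)
  rp <- simulate_read_pairs(tpl, c(g1 = 0.6, g2 = 0.4), cfg)
  for (i in seq_len(nrow(rp))) {
    ts <- tpl$sequence[tpl$id == rp$template[i]]
    hit <- grepl(rp$read1[i], ts, fixed = TRUE) ||
      grepl(revcomp(rp$read1[i]), ts, fixed = TRUE)
    expect_true(hit, info = paste("read", i))
  }
})

test_that("circular templates permit wrap-around fragments", {
  circ <- genome_set("c1", rand_dna(1000, seed = 8), circular = TRUE)
  cfg <- sim_config(300, read_length = 100, insert_mean = 400,
                    substitution_rate = 0, seed = 5)
  rp <- simulate_read_pairs(circ, c(c1 = 1), cfg)
  wrapped <- rp[rp$end > 1000, ]
  expect_gt(nrow(wrapped), 0)
  doubled <- strrep(circ$sequence, 2)
  for (i in seq_len(min(nrow(wrapped), 20))) {
    frag <- substr(doubled, wrapped$start[i] + 1, wrapped$end[i])
    if (wrapped$strand[i] == "-") frag <- revcomp(frag)
    expect_identical(substr(frag, 1, 100), wrapped$read1[i])
  }
})

test_that("template choice is proportional to abundance times length", {
  tpl <- random_genomes(3, c(2000, 4000, 8000), seed = 4)
  prof <- c(g1 = 0.5, g2 = 0.3, g3 = 0.2)
  cfg <- sim_config(100000, read_length = 80, substitution_rate = 0, seed = 11)
  rp <- simulate_read_pairs(tpl, prof, cfg)
  obs <- table(factor(rp$template, levels = tpl$id))
  w <- prof * c(2000, 4000, 8000)
  p_exp <- w / sum(w)
  gof <- chisq.test(obs, p = p_exp)
  expect_gt(gof$p.value, 0.001)
})

test_that("identical seeds give byte-identical FASTQ output", {
  tpl <- random_genomes(1, 5000, seed = 1)
  cfg <- sim_config(200, read_length = 100, seed = 99)
  d <- withr::local_tempdir()
  f1 <- write_read_pairs_fastq(simulate_read_pairs(tpl, c(g1 = 1), cfg),
                               file.path(d, "a"))
  f2 <- write_read_pairs_fastq(simulate_read_pairs(tpl, c(g1 = 1), cfg),
                               file.path(d, "b"))
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
})

test_that("simulator rejects invalid configurations and profiles", {
  tpl <- random_genomes(1, 5000, seed = 1)
  expect_error(sim_config(0), "n_pairs")
  expect_error(sim_config(10, substitution_rate = 1), "substitution_rate")
  expect_error(sim_config(10, read_length = 300, insert_mean = 200),
               "insert_mean")
  expect_error(
    simulate_read_pairs(tpl, c(gX = 1), sim_config(10, read_length = 80)),
    "missing template")
  short <- genome_set(c("a", "b"), c(rand_dna(5000, 2), rand_dna(50)))
  expect_warning(
    rp <- simulate_read_pairs(short, c(a = 0.5, b = 0.5),
                              sim_config(50, read_length = 80, seed = 1)),
    "shorter than read_length")
  expect_true(all(rp$template == "a"))
})

test_that("mock assemblies plant the advertised artifacts", {
  g <- random_genomes(2, c(4000, 4000), seed = 6)
  plan <- mock_assembly_plan(
    faithful = data.frame(genome = c("g1", "g1", "g2"),
                          start = NA, end = NA),
    chimera = data.frame(genome_a = "g1", start_a = 0, end_a = 1000,
                         genome_b = "g2", start_b = 0, end_b = 1000),
    seed = 3)
  ma <- generate_mock_assembly(g, plan)
  expect_equal(nrow(ma$scaffolds), 4L)
  expect_equal(sum(ma$truth$label == "faithful"), 3L)
  chim <- ma$scaffolds$sequence[ma$truth$label == "chimeric"]
  expect_equal(nchar(chim), 2000L)
  expect_identical(substr(chim, 1, 1000), substr(g$sequence[1], 1, 1000))
  expect_identical(substr(chim, 1001, 2000), substr(g$sequence[2], 1, 1000))
  # chimera interval validation
  bad <- mock_assembly_plan(
    chimera = data.frame(genome_a = "g1", start_a = 0, end_a = 99999,
                         genome_b = "g2", start_b = 0, end_b = 1000))
  expect_error(generate_mock_assembly(g, bad), "outside genome bounds")
})

test_that("duplicate clusters have the expected pairwise identity", {
  ma <- make_duplicate_mock(10, mutation_rate = 0.005, max_truncation = 0)
  seqs <- ma$scaffolds$sequence
  # expected pairwise identity about 1 - 2 * 0.005; direct comparison
  idents <- combn(length(seqs), 2, function(ij) {
    a <- utf8ToInt(seqs[ij[1]]); b <- utf8ToInt(seqs[ij[2]])
    mean(a == b)
  })
  expect_true(all(idents >= 0.98))
  expect_lt(mean(idents), 0.999)
})

test_that("duplicate read-pair removal keeps first occurrences only", {
  rp <- data.frame(read1 = c("AAA", "AAA", "CCC", "AAA", "AAA"),
                   read2 = c("TTT", "TTT", "GGG", "TTT", "GGC"),
                   stringsAsFactors = FALSE)
  out <- remove_duplicate_reads(rp)
  expect_equal(out$n_removed, 2L)
  # pairs identical in read1 only are both retained
  expect_true(all(c("GGC", "TTT") %in% out$pairs$read2))
  # brute-force set oracle on the pair key
  expect_equal(nrow(out$pairs),
               length(unique(paste(rp$read1, rp$read2, sep = "|"))))
  # all-unique input is the identity
  uniq <- data.frame(read1 = c("AA", "CC"), read2 = c("TT", "GG"))
  expect_identical(remove_duplicate_reads(uniq)$pairs, uniq)
})
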