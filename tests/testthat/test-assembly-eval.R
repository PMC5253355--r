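test_that("the anchor aligner recovers identity, strand and chimera blocks", {
  g <- random_genomes(2, c(4000, 4000), seed = 21)
  # exact copy: one full block, identity 100, strand +
  sc <- genome_set("copy", g$sequence[1])
  b <- align_scaffolds_to_truth(sc, g)
  expect_equal(nrow(b), 1L)
  expect_equal(b$identity, 100)
  expect_equal(b$strand, "+")
  expect_equal(c(b$s_start, b$s_end), c(0L, 4000L))
  expect_equal(b$genome_id, "g1")

  # reverse complement of an internal slice: one minus-strand block
  rc <- genome_set("rc", revcomp(substr(g$sequence[1], 101, 600)))
  b2 <- align_scaffolds_to_truth(rc, g)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$strand, "-")
  expect_equal(c(b2$s_start, b2$s_end), c(0L, 500L))
  expect_equal(c(b2$g_start, b2$g_end), c(100L, 600L))

  # chimera: blocks to both parents, none covering >= 95%
  chim <- genome_set("chim", paste0(substr(g$sequence[1], 1, 1000),
                                    substr(g$sequence[2], 1, 1000)))
  b3 <- align_scaffolds_to_truth(chim, g)
  expect_setequal(unique(b3$genome_id), c("g1", "g2"))
  cov <- tapply((b3$s_end - b3$s_start) / 2000, b3$genome_id, sum)
  expect_true(all(cov < 0.95))

  expect_error(align_scaffolds_to_truth(sc, g, min_anchor = 5000),
               "shortest genome")
})

test_that("circular genomes are aligned across the origin", {
  g <- genome_set("circ", rand_dna(3000, seed = 22), circular = TRUE)
  # a scaffold spanning the origin: last 500 nt + first 500 nt
  sc <- genome_set("span", paste0(substr(g$sequence, 2501, 3000),
                                  substr(g$sequence, 1, 500)))
  b <- align_scaffolds_to_truth(sc, g)
  expect_equal(nrow(b), 1L)
  expect_equal(b$identity, 100)
  expect_equal(b$g_start, 2500L)
  expect_equal(b$g_end, 3500L)  # may exceed length for wrap-around
  v <- classify_scaffold("span", 1000L, b)
  expect_equal(v$status, "correct")
})

test_that("show-coords rows convert to internal coordinates", {
  d <- withr::local_tempdir()
  f <- file.path(d, "coords.txt")
  writeLines(c(
    "NUCMER",
    "    [S1]     [E1]     [S2]     [E2]",
    "1\t500\t1\t500\t500\t500\t100.00\t5000\t800\t10.00\t62.50\tgA\tsC",
    "601\t800\t200\t1\t200\t200\t98.50\t5000\t800\t4.00\t25.00\tgA\tsC"
  ), f)
  b <- load_alignment_coords(f)
  expect_equal(nrow(b), 2L)
  expect_equal(b$s_start[1], 0)
  expect_equal(b$s_end[1], 500)
  expect_equal(b$g_start[1], 0)
  expect_equal(b$g_end[1], 500)
  expect_equal(b$strand, c("+", "-"))
  expect_equal(b$scaffold_id, c("sC", "sC"))
  expect_equal(b$genome_id, c("gA", "gA"))

  empty <- file.path(d, "empty.txt")
  writeLines(character(0), empty)
  expect_equal(nrow(load_alignment_coords(empty)), 0L)

  bad <- file.path(d, "bad.txt")
  writeLines("1 2 3", bad)
  expect_error(load_alignment_coords(bad), "line 1")
})

test_that("fragment-mode over-length rule fires at the 5% cutoff", {
  expect_equal(overlength_cutoff(2000, 0.05), 2100L)
  v <- classify_scaffold("s", 2100L, NULL, eval_params(),
                         fragment_mode_length = 2000L)
  expect_equal(v$status, "misassembled")
  expect_equal(v$reason, "over-length")
  # 2099 nt is not over-length (falls through to block evidence)
  v2 <- classify_scaffold("s", 2099L, NULL, eval_params(),
                          fragment_mode_length = 2000L)
  expect_equal(v2$status, "unaligned")
})

test_that("scaffold classification separates the misassembly reasons", {
  g <- random_genomes(2, c(6000, 6000), seed = 23)
  full <- genome_set("full", g$sequence[1])
  b <- align_scaffolds_to_truth(full, g)
  expect_equal(classify_scaffold("full", 6000L, b)$status, "correct")

  chim <- genome_set("chim", paste0(substr(g$sequence[1], 1, 1500),
                                    substr(g$sequence[2], 1, 1500)))
  bc <- align_scaffolds_to_truth(chim, g)
  vc <- classify_scaffold("chim", 3000L, bc)
  expect_equal(vc$status, "misassembled")
  expect_equal(vc$reason, "multi-genome")

  # non-collinear: two slices of one genome in swapped order
  swp <- genome_set("swp", paste0(substr(g$sequence[1], 3001, 4500),
                                  substr(g$sequence[1], 1, 1500)))
  bs <- align_scaffolds_to_truth(swp, g)
  vs <- classify_scaffold("swp", 3000L, bs)
  expect_equal(vs$status, "misassembled")
  expect_equal(vs$reason, "non-collinear")

  # low coverage: half the scaffold is novel sequence
  lowc <- genome_set("lowc", paste0(substr(g$sequence[1], 1, 1500),
                                    rand_dna(1500, seed = 77)))
  bl <- align_scaffolds_to_truth(lowc, g)
  vl <- classify_scaffold("lowc", 3000L, bl)
  expect_equal(vl$status, "misassembled")
  expect_equal(vl$reason, "low-coverage")

  expect_equal(classify_scaffold("none", 1000L, NULL)$status, "unaligned")
})

test_that("classification is invariant under reverse complement", {
  g <- random_genomes(2, c(6000, 6000), seed = 24)
  scaffs <- list(
    correct = substr(g$sequence[1], 501, 3500),
    chimera = paste0(substr(g$sequence[1], 1, 1500),
                     substr(g$sequence[2], 1, 1500))
  )
  for (nm in names(scaffs)) {
    s_fwd <- genome_set("x", scaffs[[nm]])
    s_rev <- genome_set("x", revcomp(scaffs[[nm]]))
    v1 <- classify_scaffold("x", nchar(scaffs[[nm]]),
                            align_scaffolds_to_truth(s_fwd, g))
    v2 <- classify_scaffold("x", nchar(scaffs[[nm]]),
                            align_scaffolds_to_truth(s_rev, g))
    expect_equal(v1$status, v2$status, info = nm)
    expect_equal(v1$reason, v2$reason, info = nm)
  }
})

test_that("N50 matches the cumulative-sum brute force", {
  expect_equal(compute_n50(c(2, 3, 4, 5, 6)), 5)
  expect_equal(compute_n50(10), 10)
  expect_equal(compute_n50(c(5, 5, 5, 5)), 5)
  expect_error(compute_n50(numeric(0)), "non-empty")
  expect_error(compute_n50(c(3, 0)), "positive")
  set.seed(31)
  for (i in 1:200) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    expect_equal(compute_n50(lens), oracle_n50(lens))
  }
})

test_that("genome recovery follows the single-sequence rule", {
  g <- random_genomes(3, c(5000, 5000, 5000), seed = 25)
  # one exact full-length copy per genome: all recovered
  ident <- genome_set(paste0("c", 1:3), g$sequence)
  b <- align_scaffolds_to_truth(ident, g)
  v <- do.call(rbind, lapply(1:3, function(i) {
    classify_scaffold(paste0("c", i), 5000L, b)
  }))
  hr <- genomes_hit_and_recovered(v, b, g)
  expect_setequal(hr$recovered, g$id)

  # genome covered only by two non-overlapping halves: hit, not recovered
  halves <- genome_set(c("h1", "h2"),
                       c(substr(g$sequence[1], 1, 2500),
                         substr(g$sequence[1], 2501, 5000)))
  bh <- align_scaffolds_to_truth(halves, g)
  vh <- do.call(rbind, lapply(c("h1", "h2"), function(id) {
    classify_scaffold(id, 2500L, bh)
  }))
  hrh <- genomes_hit_and_recovered(vh, bh, g)
  expect_true("g1" %in% hrh$hit)
  expect_false("g1" %in% hrh$recovered)
  expect_true(all(hrh$recovered %in% hrh$hit))
})

test_that("full evaluation counts planted chimeras exactly", {
  g <- random_genomes(5, 8000, seed = 26)
  plan <- mock_assembly_plan(
    faithful = data.frame(genome = rep(g$id, each = 2),
                          start = rep(c(0, 3000), 5),
                          end = rep(c(3000, 8000), 5)),
    chimera = data.frame(genome_a = c("g1", "g2", "g3"),
                         start_a = 0, end_a = 1200,
                         genome_b = c("g4", "g5", "g1"),
                         start_b = 4000, end_b = 5200),
    seed = 4)
  ma <- generate_mock_assembly(g, plan)
  ev <- evaluate_assembly(ma$scaffolds, g)
  expect_equal(ev$stats$misassembled_count, 3L)
  planted <- ma$truth$scaffold_id[ma$truth$label == "chimeric"]
  called <- ev$verdicts$scaffold_id[ev$verdicts$status == "misassembled"]
  expect_setequal(called, planted)
  expect_equal(sum(ev$summary$n_scaffolds), ev$stats$total_scaffolds)
})

test_that("identity assembly evaluation is perfect", {
  g <- random_genomes(10, c(rep(6000, 5), rep(12000, 5)), seed = 27)
  ev <- evaluate_assembly(g, g)
  expect_equal(ev$stats$misassembled_count, 0L)
  expect_equal(ev$stats$genomes_recovered, 10L)
  expect_equal(ev$stats$correct_pct, 100L)
  expect_equal(ev$stats$n50, compute_n50(nchar(g$sequence)))
})

test_that("fragment-mode evaluation bins and flags over-length scaffolds", {
  g <- random_genomes(3, 10000, seed = 28)
  fl <- fragment_genomes(g, 2000, keep_every_second = TRUE)
  # faithful single fragments plus over-length concatenations of adjacent
  # fragment windows
  overlong <- vapply(seq_len(3), function(i) {
    substr(g$sequence[i], 1, 4000)
  }, character(1))
  scaffolds <- genome_set(c(fl$fragments$id, paste0("long", 1:3)),
                          c(fl$fragments$sequence, overlong))
  ev <- evaluate_assembly(scaffolds, fl$fragments, fragment_mode_length = 2000)
  top_bin <- ev$summary[nrow(ev$summary), ]
  expect_equal(top_bin$n_scaffolds, 3L)
  expect_equal(top_bin$pct_misassembled, 100L)
  other <- ev$summary[-nrow(ev$summary), ]
  expect_true(all(other$pct_misassembled[other$n_scaffolds > 0] == 0))
})

test_that("read mapping back reports concordance and multi-mapping", {
  g <- random_genomes(1, 8000, seed = 29)
  cfg <- sim_config(60, read_length = 80, substitution_rate = 0, seed = 6)
  rp <- simulate_read_pairs(g, c(g1 = 1), cfg)
  mr <- map_reads_back(rp, g)
  expect_equal(mr$pct_concordant, 100)
  expect_equal(mr$pct_multi_diff, 0)
  # duplicated scaffold forces placements on different scaffolds
  dup <- genome_set(c("a", "b"), rep(g$sequence, 2))
  mr2 <- map_reads_back(rp, dup)
  expect_gt(mr2$pct_multi_diff, 0)
  # disjoint scaffolds share no 31-mer with the reads: nothing maps
  other <- random_genomes(1, 5000, seed = 777, prefix = "z")
  mr3 <- map_reads_back(rp, other)
  expect_equal(mr3$pct_concordant, 0)
})
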