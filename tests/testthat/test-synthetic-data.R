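test_that("genome and annotation generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5L, n_genes = 8L, n_circ_genes = 4L)
  a <- generate_genome_annotation(cfg)
  b <- generate_genome_annotation(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_equal(a$exons, b$exons)
  expect_equal(a$truth, b$truth)
  # byte-identical serialised annotation
  fa <- withr::local_tempfile(fileext = ".refflat")
  fb <- withr::local_tempfile(fileext = ".refflat")
  write_refflat(a$exons, fa); write_refflat(b$exons, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("an empty gene model is a valid (empty) simulation", {
  sim <- generate_genome_annotation(sim_config(n_genes = 0L,
                                               n_circ_genes = 0L))
  expect_equal(nrow(sim$exons), 0L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("configured flanking-intron inflation is realised in the generated annotation", {
  cfg <- sim_config(seed = 3L, n_genes = 60L, n_circ_genes = 60L,
                    circ_flank_intron_factor = 10)
  sim <- generate_genome_annotation(cfg)
  introns <- derive_introns(sim$exons)
  flank <- other <- numeric(0)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i]
    itx <- introns[transcript_id == tr$transcript_id]
    f_ord <- c(tr$acceptor_ordinal - 1L, tr$donor_ordinal)
    flank <- c(flank, itx[ordinal %in% f_ord & ordinal != 1L, end - start])
    other <- c(other, itx[!ordinal %in% f_ord & ordinal != 1L, end - start])
  }
  ratio <- mean(flank) / mean(other)
  expect_gt(ratio, 5)    # within 2x of the configured 10x
  expect_lt(ratio, 20)
})

test_that("planted junction-crossing reads are recovered by the string-search oracle", {
  run <- toy_run()
  sim <- run$sim; reads <- run$reads
  oracle <- oracle_junction_counts(reads, sim,
                                   min_anchor = run$index$config$min_anchor)
  # every truth-tagged junction-crossing pair is seen by the oracle:
  # pairs are tagged j1/j2 at generation time independently of anchors,
  # so oracle counts (anchored) can only be <= tag counts, and detected
  # counts equal oracle counts exactly (checked in the acceptance suite)
  tags <- reads$truth[truth_class == "circ"]
  tag_counts <- tags[j1 | j2, .N, by = .(key = origin)]
  m <- merge(oracle, tag_counts, by = "key")
  expect_equal(nrow(m), nrow(sim$truth))
  expect_true(all(m$n_pairs <= m$N))
  expect_true(all(m$n_pairs >= 20))   # abundant enough for detection tests
})

test_that("a circRNA planted at zero abundance contributes no circular reads", {
  cfg <- sim_config(seed = 9L, n_genes = 6L, n_circ_genes = 2L,
                    circ_read_pairs = 0L, n_read_pairs = 2000L)
  sim <- generate_genome_annotation(cfg)
  reads <- simulate_read_pairs(sim)
  expect_equal(sum(reads$truth$truth_class == "circ"), 0L)
})

test_that("fully overlapping mates both cross the junction when the fragment equals the read length", {
  cfg <- sim_config(seed = 13L, n_genes = 4L, n_circ_genes = 2L,
                    circ_read_pairs = 200L, n_read_pairs = 1500L,
                    fragment_mean = 75, fragment_sd = 0)
  sim <- generate_genome_annotation(cfg)
  reads <- simulate_read_pairs(sim)
  circ <- reads$truth[truth_class == "circ"]
  expect_true(all(circ$j1 == circ$j2))
  expect_gt(sum(circ$j1), 0)
})

test_that("fraction loading governs where circular reads land", {
  cfg <- sim_config(seed = 21L, n_genes = 6L, n_circ_genes = 3L,
                    n_read_pairs = 3000L, circ_read_pairs = 300L,
                    fraction_read_pairs = 2000L)
  sim <- generate_genome_annotation(cfg)
  # all circ mass on fraction 1: fractions 2..8 contain no circular reads
  sets <- simulate_fractions(sim,
                             circ_loading = c(1, rep(0, 7)),
                             linear_loading = rep(0.1, 8))
  for (f in paste0("f", 2:8))
    expect_equal(sum(sets[[f]]$truth$truth_class == "circ"), 0L)
  expect_gt(sum(sets$f1$truth$truth_class == "circ"), 0L)
  # free mass 1.0: circular reads appear only in the total set
  sets2 <- simulate_fractions(sim, circ_loading = rep(0, 8),
                              linear_loading = rep(0.1, 8))
  for (f in paste0("f", 1:8))
    expect_equal(sum(sets2[[f]]$truth$truth_class == "circ"), 0L)
  expect_gt(sum(sets2$total$truth$truth_class == "circ"), 0L)
})

test_that("multinomial allocation matches its expectation within 3 sigma", {
  set.seed(31)
  n <- 10000L
  draw <- as.integer(stats::rmultinom(1, n, c(0.5, 0.5, rep(0, 6))))
  sigma <- sqrt(n * 0.5 * 0.5)
  expect_lt(abs(draw[1] - 5000), 3 * sigma)
  expect_equal(sum(draw[3:8]), 0L)
})

test_that("NET-seq simulation: equal dwell factors and no stalls give a flat expected profile", {
  cfg <- sim_config(seed = 17L, n_genes = 5L, n_circ_genes = 0L,
                    netseq_exon_factor = 2, netseq_intron_factor = 2,
                    netseq_stall_height = 1, netseq_accel = 0)
  sim <- generate_genome_annotation(cfg)
  ns <- simulate_netseq(sim)
  mu <- ns$expected[[1]]
  gene_vals <- as.numeric(mu)[as.numeric(mu) > 0]
  expect_true(all(abs(gene_vals - gene_vals[1]) < 1e-12))
})

test_that("NET-seq simulation recovers the exon/intron dwell ratio and replicate averaging halves the variance", {
  cfg <- sim_config(seed = 23L, n_genes = 100L, n_circ_genes = 0L,
                    netseq_exon_factor = 3, netseq_intron_factor = 1,
                    netseq_stall_height = 1)
  sim <- generate_genome_annotation(cfg)
  ns <- simulate_netseq(sim)
  comb <- combine_replicates(list(ns$rep1, ns$rep2))
  exonic <- sim$exons[, .(chrom, start, end)]
  intronic <- derive_introns(sim$exons)[, .(chrom, start, end)]
  ex_d <- sum(region_density(comb, exonic) * (exonic$end - exonic$start)) /
    sum(exonic$end - exonic$start)
  in_d <- sum(region_density(comb, intronic) *
                (intronic$end - intronic$start)) /
    sum(intronic$end - intronic$start)
  expect_lt(abs(ex_d / in_d - 3), 0.3)   # within 10% of the planted 3x

  # averaging two independent Poisson replicates halves the variance
  intron_pos <- as.numeric(S4Vectors::window(
    ns$rep1[[1]], intronic$start[1] + 1L, intronic$end[1]))
  intron_pos2 <- as.numeric(S4Vectors::window(
    ns$rep2[[1]], intronic$start[1] + 1L, intronic$end[1]))
  v_single <- stats::var(c(intron_pos, intron_pos2))
  v_mean <- stats::var((intron_pos + intron_pos2) / 2)
  expect_lt(abs(v_mean / v_single - 0.5), 0.2)
})

test_that("planted seed matches are present in the circle sequence at the recorded positions", {
  st <- toy_sites()
  sim <- st$sim
  for (i in seq_len(nrow(st$site_truth))) {
    tr_site <- st$site_truth[i]
    tr <- sim$truth[key == tr_site$key]
    cs <- circle_sequence(sim, tr)
    wrapped <- paste0(cs, substr(cs, 1, 5))
    target <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gsub("U", "T", tr_site$seed_hex))))
    expect_equal(substr(wrapped, tr_site$circ_pos, tr_site$circ_pos + 5L),
                 target)
  }
  # both filter-positives and filter-negatives are planted
  expect_gt(sum(st$site_truth$ago_supported), 0)
  expect_gt(sum(!st$site_truth$ago_supported), 0)
  expect_equal(sum(st$site_truth$junction_spanning), 1L)
})
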