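# A tiny hand-built locus for exact detector checks: one 4-exon
# plus-strand gene, circle over exons 2-3.
detect_fixture <- function() {
  exons <- toy_exons()[transcript_id == "TXA"]
  genome <- toy_genome()
  det <- detector_config(k = 40L, min_anchor = 8L, max_mismatches = 1L,
                         read_length = 50L)
  index <- build_backsplice_index(exons, genome, det)
  list(exons = exons, genome = genome, det = det, index = index)
}

test_that("the candidate library enumerates all ordinal pairs and truncates short flanks", {
  fx <- detect_fixture()
  expect_equal(nrow(fx$index$junctions), 10L)  # C(4,2) + 4 = 10 pairs a <= d
  # exon 4 is 50 nt; with k = 60 its flank is truncated to the exon length
  idx60 <- build_backsplice_index(fx$exons, fx$genome,
                                  detector_config(k = 60L,
                                                  read_length = 68L))
  j44 <- idx60$junctions[acceptor_ordinal == 4 & donor_ordinal == 4]
  expect_equal(j44$junc_point, 50L)
  expect_equal(nchar(j44$junc_seq), 50L + 50L)

  # two isoforms sharing an exon pair collapse to one junction key
  two_iso <- read_refflat(c(
    paste("G", "T1", "chrT", "+", 0, 500, 0, 500, 3,
          "0,200,400,", "100,300,500,", sep = "\t"),
    paste("G", "T2", "chrT", "+", 0, 500, 0, 500, 3,
          "0,200,400,", "100,300,500,", sep = "\t")))
  idx2 <- build_backsplice_index(two_iso, toy_genome(),
                                 detector_config(k = 30, read_length = 40))
  j <- idx2$junctions[acceptor_ordinal == 2 & donor_ordinal == 3]
  expect_equal(nrow(j), 1L)
  expect_setequal(strsplit(j$transcript_ids, ",")[[1]], c("T1", "T2"))
})

test_that("pairs on the linear transcriptome are discarded and back-splice reads survive", {
  fx <- detect_fixture()
  txseq <- as.character(transcript_sequences(fx$exons, fx$genome))
  linear <- c(transcript_sequences(fx$exons, fx$genome), fx$genome)
  # pair fully inside one exon
  r_exonic <- substr(txseq, 10, 59)
  # pair spanning the canonical exon1-exon2 junction (transcript pos 76..125)
  r_splice <- substr(txseq, 76, 125)
  # junction read across the back-splice of circle exons 2..3
  j23 <- fx$index$junctions[acceptor_ordinal == 2 & donor_ordinal == 3]
  circ <- j23$circ_seq
  r_bs <- paste0(substr(circ, nchar(circ) - 24, nchar(circ)),
                 substr(circ, 1, 25))
  mk <- function(a, b) list(read1 = Biostrings::DNAStringSet(a),
                            read2 = Biostrings::DNAStringSet(b))
  lab <- classify_linear(mk(c(r_exonic, r_splice, r_bs),
                            c(r_splice, r_exonic, r_exonic)),
                         linear, fx$det)
  expect_equal(lab, c("linear", "linear", "candidate"))
})

test_that("junction hits honour anchors, mismatches and the uniqueness rule", {
  fx <- detect_fixture()
  j23 <- fx$index$junctions[acceptor_ordinal == 2 & donor_ordinal == 3]
  circ <- j23$circ_seq
  L <- nchar(circ)
  centred <- paste0(substr(circ, L - 24, L), substr(circ, 1, 25))  # 25/25
  skewed <- paste0(substr(circ, L - 4, L), substr(circ, 1, 45))    # 5/45
  hits_c <- detect_junction_reads(Biostrings::DNAStringSet(centred),
                                  fx$index, fx$det)
  expect_equal(hits_c$key, j23$key)
  hits_s <- detect_junction_reads(Biostrings::DNAStringSet(skewed),
                                  fx$index, fx$det)
  expect_equal(nrow(hits_s), 0L)  # 5 < min_anchor on the donor side

  # one substitution is tolerated and reported
  mut <- centred
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
  hits_m <- detect_junction_reads(Biostrings::DNAStringSet(mut),
                                  fx$index, fx$det)
  expect_equal(hits_m$key, j23$key)
  expect_equal(hits_m$mismatches, 1L)

  # a read matching two junction keys equally well is discarded
  amb_index <- fx$index
  amb_index$junctions <- rbind(
    j23, copy(j23)[, key := "chrT:9999:10999:+"])
  hits_a <- detect_junction_reads(Biostrings::DNAStringSet(centred),
                                  amb_index, fx$det)
  expect_equal(nrow(hits_a), 0L)
})

test_that("mates are verified inside the circle, including mates that also cross the junction", {
  fx <- detect_fixture()
  j23 <- fx$index$junctions[acceptor_ordinal == 2 & donor_ordinal == 3]
  circ <- j23$circ_seq
  L <- nchar(circ)
  junc_read <- paste0(substr(circ, L - 24, L), substr(circ, 1, 25))
  inside <- substr(circ, 40, 89)
  outside <- as.character(Biostrings::subseq(fx$genome[[1]], 600, 649))
  also_junc <- paste0(substr(circ, L - 19, L), substr(circ, 1, 30))
  reads <- Biostrings::DNAStringSet(rep(junc_read, 3))
  hits <- detect_junction_reads(reads, fx$index, fx$det)
  expect_equal(nrow(hits), 3L)
  mates <- Biostrings::DNAStringSet(c(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(inside))),
    outside, also_junc))
  kept <- verify_mate_inside(hits, mates, fx$index, fx$det)
  expect_setequal(kept$read_idx, c(1L, 3L))
})

test_that("JPM normalisation and the abundance filter behave exactly at the boundary", {
  counts <- kdt(sample_id = c("s1", "s1", "s2"),
                       key = c("k1", "k2", "k1"),
                       n_pairs = c(5L, 18L, 0L))
  jm <- count_and_normalize(counts, c(s1 = 50e6, s2 = 90e6))
  expect_equal(jm[key == "k1" & sample_id == "s1", jpm], 0.1)
  expect_equal(jm[key == "k2", jpm], 0.36)
  expect_equal(nrow(jm[n_pairs == 0]), 0L)   # zero-count records omitted
  expect_error(count_and_normalize(counts, c(s1 = 0, s2 = 90e6)), "zero")

  sheet <- data.table(sample_id = c("s1", "s2"), cell_type = "hek")
  recs <- kdt(sample_id = c("s1", "s2", "s1", "s1"),
                     key = c("a", "a", "b", "c"),
                     jpm = c(0.05, 0.20, 0.10, 0.05))
  # mean(0.05, 0.20) = 0.125 kept; b: mean(0.10, 0) = 0.05 dropped;
  # exact 0.1 kept when it is the cell-type mean
  kept <- filter_by_abundance(recs, sheet, threshold = 0.1)
  expect_equal(kept, "a")
  kept_one <- filter_by_abundance(
    kdt(sample_id = "s1", key = "d", jpm = 0.1),
    data.table(sample_id = "s1", cell_type = "hek"))
  expect_equal(kept_one, "d")

  # polysome-fraction rescue: total mean 0.05 but fraction mean 0.12
  fm <- kdt(key = "c", total = 0.05)
  for (f in paste0("f", 1:8)) fm[, (f) := 0.12]
  fm[, `:=`(free_star_raw = 0, free_star = 0)]
  kept_r <- filter_by_abundance(recs, sheet, threshold = 0.1,
                                fraction_matrix = fm)
  expect_setequal(kept_r, c("a", "c"))
})

test_that("JPM is invariant under duplicating reads and doubling mapped totals", {
  counts <- kdt(sample_id = "s", key = "k", n_pairs = 7L)
  a <- count_and_normalize(counts, c(s = 1e7))
  b <- count_and_normalize(copy(counts)[, n_pairs := n_pairs * 2L],
                           c(s = 2e7))
  expect_equal(a$jpm, b$jpm)
})

test_that("overlap summaries reproduce percentage arithmetic on identifier sets", {
  a <- paste0("g", 1:395); b <- paste0("g", 1:500)
  denom <- paste0("g", 1:621)
  ov <- overlap_summary(a, b, denom)
  expect_equal(ov$n_overlap, 395L)
  expect_equal(ov$percent, 64)
  expect_equal(overlap_summary(paste0("x", 1:111), paste0("x", 1:200),
                               paste0("x", 1:239))$percent, 46)
  expect_equal(overlap_summary(a, a, a)$percent, 100)
  expect_error(overlap_summary(a, b, character(0)), "denominator")
})

test_that("detected junctions never leave the candidate library and match the planted truth", {
  run <- toy_run()
  expect_true(all(run$records$key %in% run$index$junctions$key))
  expect_gte(run$recall, 0.9)
  expect_gte(run$precision, 0.9)
})
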