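test_that("RefFlat parsing applies the 0-based half-open convention and strand-aware ordinals", {
  ex <- read_refflat(paste("G1", "T1", "chr1", "+", 0, 300, 0, 300, 2,
                           "0,200,", "100,300,", sep = "\t"))
  expect_equal(ex$start, c(0L, 200L))
  expect_equal(ex$end, c(100L, 300L))
  expect_equal(ex$ordinal, c(1L, 2L))

  ex_minus <- read_refflat(paste("G1", "T1", "chr1", "-", 0, 300, 0, 300, 2,
                                 "0,200,", "100,300,", sep = "\t"))
  expect_equal(ex_minus$ordinal, c(2L, 1L))  # right-most exon is ordinal 1

  expect_error(
    read_refflat(paste("G1", "T1", "chr1", "+", 0, 300, 0, 300, 3,
                       "0,200,", "100,300,", sep = "\t")),
    "malformed.*line 1")
  expect_error(
    read_refflat(paste("G1", "T1", "chr1", ".", 0, 300, 0, 300, 2,
                       "0,200,", "100,300,", sep = "\t")),
    "strand")
})

test_that("RefFlat writing round-trips and feature lengths add up to the transcript span", {
  exons <- toy_exons()
  path <- withr::local_tempfile(fileext = ".refflat")
  write_refflat(exons, path)
  back <- read_refflat(path)
  setkey(back, transcript_id, start)
  orig <- data.table::copy(exons); setkey(orig, transcript_id, start)
  expect_equal(back, orig)

  introns <- derive_introns(exons)
  for (tx in unique(exons$transcript_id)) {
    e <- exons[transcript_id == tx]
    i <- introns[transcript_id == tx]
    expect_equal(sum(e$end - e$start) + sum(i$end - i$start),
                 e$tx_end[1] - e$tx_start[1])
  }
})

test_that("introns take strand-aware ordinals and single-exon transcripts have none", {
  plus <- read_refflat(paste("G", "T", "c", "+", 0, 500, 0, 500, 3,
                             "0,200,400,", "100,300,500,", sep = "\t"))
  ip <- derive_introns(plus)
  expect_equal(ip[order(ordinal), .(start, end, ordinal)],
               data.table(start = c(100L, 300L), end = c(200L, 400L),
                          ordinal = 1:2))

  minus <- read_refflat(paste("G", "T", "c", "-", 0, 500, 0, 500, 3,
                              "0,200,400,", "100,300,500,", sep = "\t"))
  im <- derive_introns(minus)
  # transcription order is right-to-left: intron 1 is the genomic-right gap
  expect_equal(im[ordinal == 1L, .(start, end)],
               data.table(start = 300L, end = 400L))
  expect_equal(im[ordinal == 2L, .(start, end)],
               data.table(start = 100L, end = 200L))

  single <- read_refflat(paste("G", "T", "c", "+", 0, 100, 0, 100, 1,
                               "0,", "100,", sep = "\t"))
  expect_equal(nrow(derive_introns(single)), 0L)
})

test_that("interval intersection honours the minimum query-overlap fraction", {
  q <- data.table(chrom = "c", start = 0L, end = 100L)
  expect_equal(nrow(intersect_intervals(
    q, data.table(chrom = "c", start = 0L, end = 80L), 0.75)), 1L)
  expect_equal(nrow(intersect_intervals(
    q, data.table(chrom = "c", start = 0L, end = 74L), 0.75)), 0L)
  # ~20 nt site with half its length overlapping is kept at fraction 0.5
  q20 <- data.table(chrom = "c", start = 0L, end = 20L)
  expect_equal(nrow(intersect_intervals(
    q20, data.table(chrom = "c", start = 10L, end = 40L), 0.5)), 1L)
  expect_equal(nrow(intersect_intervals(
    data.table(chrom = character(), start = integer(), end = integer()),
    q20, 0.5)), 0L)
})

test_that("interval intersection agrees with an exhaustive pairwise oracle", {
  set.seed(11)
  q <- data.table(chrom = sample(c("c1", "c2"), 60, TRUE),
                  start = sample(0:500, 60, TRUE))
  q[, end := start + sample(1:80, 60, TRUE)]
  s <- data.table(chrom = sample(c("c1", "c2"), 80, TRUE),
                  start = sample(0:500, 80, TRUE))
  s[, end := start + sample(1:80, 80, TRUE)]
  frac <- 0.5
  got <- intersect_intervals(q, s, frac)
  setkey(got, qidx, sidx)
  oracle <- list()
  for (i in seq_len(nrow(q))) for (j in seq_len(nrow(s))) {
    if (q$chrom[i] != s$chrom[j]) next
    ov <- min(q$end[i], s$end[j]) - max(q$start[i], s$start[j])
    if (ov > 0 && ov >= frac * (q$end[i] - q$start[i]))
      oracle[[length(oracle) + 1L]] <- data.table(qidx = i, sidx = j,
                                                  overlap_nt = ov)
  }
  oracle <- rbindlist(oracle); setkey(oracle, qidx, sidx)
  expect_equal(got, oracle)
  # overlap_nt is symmetric in query/subject roles
  swapped <- intersect_intervals(s, q, 1e-9)
  m <- merge(got[, .(qidx, sidx, overlap_nt)],
             swapped[, .(qidx = sidx, sidx = qidx, ov2 = overlap_nt)],
             by = c("qidx", "sidx"))
  expect_equal(m$overlap_nt, m$ov2)
})

test_that("FPKM follows count / (exonic kb x mapped millions) with union exon lengths", {
  exons <- read_refflat(c(
    paste("G1", "T1", "c", "+", 0, 1000, 0, 1000, 1, "0,", "1000,",
          sep = "\t"),
    # second isoform overlapping the first: union length still 1000
    paste("G1", "T2", "c", "+", 0, 1000, 0, 1000, 1, "0,", "1000,",
          sep = "\t")))
  counts <- data.table(gene = "G1", sample_id = c("s1", "s2"),
                       count = c(10, 0))
  expr <- compute_fpkm(counts, exons, c(s1 = 1e6, s2 = 1e6))
  expect_equal(expr[sample_id == "s1", fpkm], 10)
  expect_equal(expr[sample_id == "s2", fpkm], 0)
  expect_equal(expressed_genes(expr), "G1")  # mean 5 >= 1

  # mean over samples decides the expressed flag: 0.5 and 1.6 -> 1.05
  counts2 <- data.table(gene = "G1", sample_id = c("s1", "s2"),
                        count = c(0.5, 1.6))
  expr2 <- compute_fpkm(counts2, exons, c(s1 = 1e6, s2 = 1e6))
  expect_equal(expressed_genes(expr2), "G1")
  expect_equal(expressed_genes(expr2, threshold = 1.1), character(0))
  expect_error(compute_fpkm(counts, exons, c(s1 = 0, s2 = 1e6)), "> 0")
})

test_that("transcript-to-genome mapping splits segments across exons strand-aware", {
  exons <- toy_exons()
  ea <- exons[transcript_id == "TXA"]
  # 10-nt segment straddling the first splice boundary (exon1 98..100 +
  # exon2 first 7 nt)
  pieces <- map_transcript_to_genome(ea, 98L, 10L)
  expect_equal(pieces$start, c(97L, 200L))
  expect_equal(pieces$end, c(100L, 207L))
  eb <- exons[transcript_id == "TXB"]
  # minus strand: transcript position 1 is the genomic end of the
  # right-most exon
  p1 <- map_transcript_to_genome(eb, 1L, 5L)
  expect_equal(p1$start, 1355L)
  expect_equal(p1$end, 1360L)
})

test_that("GTF exon features convert to the same models as RefFlat", {
  gtf <- c(
    paste("chrT", "src", "exon", 1, 100, ".", "+", ".",
          "gene_id \"GA\"; gene_name \"GA\"; transcript_id \"TXA\";",
          sep = "\t"),
    paste("chrT", "src", "exon", 201, 300, ".", "+", ".",
          "gene_id \"GA\"; gene_name \"GA\"; transcript_id \"TXA\";",
          sep = "\t"),
    paste("chrT", "src", "gene", 1, 300, ".", "+", ".",
          "gene_id \"GA\"; gene_name \"GA\";", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  ex <- read_gtf_exons(path)
  expect_equal(nrow(ex), 2L)            # the gene feature is ignored
  expect_equal(ex$start, c(0L, 200L))   # 1-based closed -> 0-based half-open
  expect_equal(ex$end, c(100L, 300L))
  expect_equal(ex$ordinal, c(1L, 2L))
  ref <- read_refflat(paste("GA", "TXA", "chrT", "+", 0, 300, 0, 300, 2,
                            "0,200,", "100,300,", sep = "\t"))
  expect_equal(ex[, .(gene, transcript_id, chrom, strand, start, end,
                      ordinal)],
               ref[, .(gene, transcript_id, chrom, strand, start, end,
                       ordinal)])
})
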