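# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

# default-condition simulate-and-detect run (the study conditions:
# 20 genes, 10 planted circRNAs, 50k error-free pairs)
toy_run <- function() {
  if (is.null(.fixture_cache$run))
    .fixture_cache$run <- run_toy_pipeline(seed = 1L)
  .fixture_cache$run
}

# regulatory-site planting on the default simulation
toy_sites <- function() {
  if (is.null(.fixture_cache$sites)) {
    sim <- generate_genome_annotation(sim_config(seed = 1L))
    .fixture_cache$sites <- simulate_regulatory_sites(sim)
  }
  .fixture_cache$sites
}

# two-transcript toy annotation used across unit tests:
#   TXA (+): exons [0,100) [200,300) [400,500) [650,700)
#   TXB (-): exons [1000,1100) [1300,1360)
toy_refflat_lines <- function() {
  c(paste("GA", "TXA", "chrT", "+", 0, 700, 0, 700, 4,
          "0,200,400,650,", "100,300,500,700,", sep = "\t"),
    paste("GB", "TXB", "chrT", "-", 1000, 1360, 1000, 1360, 2,
          "1000,1300,", "1100,1360,", sep = "\t"))
}

toy_exons <- function() read_refflat(toy_refflat_lines())

# deterministic toy genome covering chrT
toy_genome <- function() {
  if (is.null(.fixture_cache$genome)) {
    set.seed(7L)
    .fixture_cache$genome <- Biostrings::DNAStringSet(c(
      chrT = paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                   collapse = "")))
  }
  .fixture_cache$genome
}

# independent enumeration oracle for the two-sided Mann-Whitney test:
# all C(n1+n2, n1) assignments of the pooled values
mw_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# independent circular-ORF oracle: explicit triple concatenation and a
# linear scan, no modular arithmetic shared with the implementation
orf_oracle <- function(s, start_codons = c("ATG", "CTG", "GTG")) {
  s <- toupper(gsub("U", "T", s))
  L <- nchar(s)
  concat <- strrep(s, 4)   # every start position gets 3 full revolutions
  stops <- c("TAG", "TAA", "TGA")
  rows <- list()
  for (p in 1:L) {
    if (!substr(concat, p, p + 2) %in% start_codons) next
    window <- substr(concat, p, p + 3 * L - 1)   # the three rounds
    stop_off <- NA_integer_
    for (q in seq(4, 3 * L - 2, by = 3)) {
      if (substr(window, q, q + 2) %in% stops) { stop_off <- q; break }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = p,
      stop_pos = if (is.na(stop_off)) NA_integer_ else
        ((p + stop_off - 2) %% L) + 1L,
      n_codons = if (is.na(stop_off)) NA_integer_ else
        (stop_off - 1) / 3 + 1,
      infinite_loop = is.na(stop_off))
  }
  if (!length(rows))
    return(data.frame(start = integer(), stop_pos = integer(),
                      n_codons = integer(), infinite_loop = logical()))
  do.call(rbind, rows)
}

random_circle <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# data.table() interprets an argument named `key` as the table key, so
# tables carrying a `key` column are built from plain lists
kdt <- function(...) data.table::as.data.table(list(...))

# cached recovery experiments shared between unit and acceptance suites

# 20 seeded annotation simulations: does each reproduce acceptor argmax 2,
# span mode 2, and pooled flanking-intron inflation at P < 0.01?
feature_recovery_runs <- function() {
  if (!is.null(.fixture_cache$feat_rec)) return(.fixture_cache$feat_rec)
  ok <- 0L
  for (s in 1:20) {
    cfg <- sim_config(seed = 1000L + s, n_genes = 60L, n_circ_genes = 30L,
                      circ_flank_intron_factor = 5)
    sim <- generate_genome_annotation(cfg)
    ef <- exon_position_frequency(sim$exons[gene %in% sim$truth$gene])
    prof <- backsplice_position_profile(sim$truth$acceptor_ordinal, ef)
    argmax_ok <- prof[which.max(frequency), position] == 2L
    spans <- circ_exon_span_distribution(sim$truth)
    span_ok <- spans[which.max(count), span] == 2L
    iso <- sim$truth[, .(key, transcript_id, acceptor_ordinal,
                         donor_ordinal)]
    feats <- circ_features(iso, sim$exons)
    flanks <- feats[role %in% c("flank_upstream", "flank_downstream")]
    flanks[, class_ := "all"]
    ls <- length_stats(flanks, sim$exons[!gene %in% sim$truth$gene])
    p_ok <- all(ls$p < 0.01) && all(ls$direction == "circ")
    ok <- ok + as.integer(argmax_ok && span_ok && p_ok)
  }
  .fixture_cache$feat_rec <- ok
  ok
}

# NET-seq dwell recovery: circ genes get 2x exon dwell and 0.5x intron
# dwell; returns the position-adjusted comparison table and the metagene
# stall ratio measured on a stall-only simulation
netseq_recovery <- function() {
  if (!is.null(.fixture_cache$net_rec)) return(.fixture_cache$net_rec)
  cfg <- sim_config(seed = 62L, n_genes = 60L, n_circ_genes = 20L,
                    netseq_gene_rate = 0.5,
                    netseq_exon_factor = 2, netseq_intron_factor = 2,
                    netseq_stall_height = 1,
                    netseq_circ_exon_factor = 4,
                    netseq_circ_intron_factor = 1)
  sim <- generate_genome_annotation(cfg)
  ns <- simulate_netseq(sim)
  track <- cap_track(combine_replicates(list(ns$rep1, ns$rep2)), 10)
  iso <- sim$truth[, .(key, transcript_id, acceptor_ordinal,
                       donor_ordinal)]
  feats <- circ_features(iso, sim$exons)
  feats[, class_ := "all"]
  introns <- derive_introns(sim$exons)
  geno <- rbind(
    merge(feats[kind == "exon"],
          sim$exons[, .(transcript_id, ordinal, chrom, start, end)],
          by = c("transcript_id", "ordinal")),
    merge(feats[kind == "intron"],
          introns[, .(transcript_id, ordinal, chrom, start, end)],
          by = c("transcript_id", "ordinal")))
  ref_ex <- sim$exons[!gene %in% sim$truth$gene,
                      .(chrom, start, end, ordinal)]
  ref_in <- introns[!gene %in% sim$truth$gene,
                    .(chrom, start, end, ordinal)]
  ref <- rbind(ref_ex[, `:=`(kind = "exon")],
               ref_in[, `:=`(kind = "intron")])
  ref <- merge(ref, unique(geno[, .(kind, role, ordinal, class_)]),
               by = c("kind", "ordinal"), allow.cartesian = TRUE)
  cmp <- compare_position_adjusted(track, geno, ref)

  cfg2 <- sim_config(seed = 63L, n_genes = 60L, n_circ_genes = 0L,
                     netseq_gene_rate = 1,
                     netseq_exon_factor = 1, netseq_intron_factor = 1,
                     netseq_stall_height = 4, netseq_stall_width = 5)
  sim2 <- generate_genome_annotation(cfg2)
  ns2 <- simulate_netseq(sim2)
  track2 <- combine_replicates(list(ns2$rep1, ns2$rep2))
  regions <- sim2$exons[ordinal > 1, .(chrom, start, end, strand)]
  prof <- metagene_profile(track2, regions, exon_bins = 100L,
                           flank = 100L)
  up <- prof[segment == "upstream"]
  stall_ratio <- up[position > 95, mean(mean_signal)] /
    up[position >= 30 & position <= 60, mean(mean_signal)]
  .fixture_cache$net_rec <- list(cmp = cmp, stall_ratio = stall_ratio,
                                 planted_height = 4)
  .fixture_cache$net_rec
}
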