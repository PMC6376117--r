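# Deterministic synthetic data: multi-exon gene models with planted
# back-spliced circRNAs, paired-end reads, polysome-fraction read sets,
# NET-seq coverage and regulatory sites. Every draw is governed by
# config$seed (fixed offsets separate the operations' streams), so all
# outputs are byte-identical across runs.

#' Simulation configuration
#'
#' Defaults describe the toy study conditions used throughout the test
#' suite: 20 multi-exon genes, 10 of them producing a planted circRNA
#' abundant enough to leave well over 20 junction-crossing read pairs in a
#' 50,000-pair library, error-free reads, acceptor positions biased to
#' ordinal 2, exon spans peaked at 2, and 5-fold inflated circRNA-flanking
#' introns. Lengths are lognormal: internal exons around 120 nt,
#' terminal exons longer, introns around 800 nt with a longer first
#' intron, mirroring typical mammalian gene architecture.
#'
#' @param seed integer master seed; fixes every random draw.
#' @param n_genes,n_circ_genes number of genes and of circRNA-producing
#'   genes among them.
#' @param exon_count_min,exon_count_mean exon count per gene is
#'   `exon_count_min` plus a Poisson draw with the complementary mean.
#' @param internal_exon_meanlog,internal_exon_sdlog lognormal internal
#'   exon lengths (nt).
#' @param terminal_exon_meanlog,terminal_exon_sdlog lognormal first/last
#'   exon lengths (nt).
#' @param intron_meanlog,intron_sdlog lognormal intron lengths (nt).
#' @param first_intron_factor multiplier on intron 1 length.
#' @param circ_flank_intron_factor multiplier on the two introns flanking
#'   a planted circle.
#' @param circ_acceptor_bias named probability vector: acceptor ordinal
#'   position mass (must sum to 1).
#' @param circ_span_dist named probability vector: circle exon-span mass
#'   (must sum to 1).
#' @param circ_read_pairs expected read pairs drawn from each planted
#'   circle in the main library.
#' @param read_length,n_read_pairs read length (nt) and total pairs in the
#'   main library.
#' @param fragment_mean,fragment_sd normal fragment-size model (nt).
#' @param error_rate per-base uniform substitution probability.
#' @param circ_fraction_loading,linear_fraction_loading per-class
#'   probability that a molecule's read lands in ribosomal fractions 1..8;
#'   the residue is the free (non-ribosomal) pool sampled only by the
#'   total-cytoplasmic library. Each must sum to <= 1.
#' @param fraction_read_pairs pairs per fraction library (and per total).
#' @param netseq_gene_rate baseline expected NET-seq counts per nt.
#' @param netseq_exon_factor,netseq_intron_factor Pol II dwell multipliers
#'   for exons and introns.
#' @param netseq_stall_height,netseq_stall_width boundary stall bump:
#'   dwell multiplier applied within `stall_width` nt of exon boundaries.
#' @param netseq_accel per-gene exponential acceleration of Pol II along
#'   the gene body (0 = none).
#' @param netseq_circ_exon_factor,netseq_circ_intron_factor optional
#'   overrides for circRNA-producing genes (default: same as other genes).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L, n_circ_genes = 10L,
                       exon_count_min = 5L, exon_count_mean = 9,
                       internal_exon_meanlog = log(120),
                       internal_exon_sdlog = 0.35,
                       terminal_exon_meanlog = log(300),
                       terminal_exon_sdlog = 0.4,
                       intron_meanlog = log(800), intron_sdlog = 0.6,
                       first_intron_factor = 3,
                       circ_flank_intron_factor = 5,
                       circ_acceptor_bias = c("2" = 0.6, "3" = 0.2,
                                              "4" = 0.12, "5" = 0.08),
                       circ_span_dist = c("1" = 0.15, "2" = 0.5,
                                          "3" = 0.2, "4" = 0.15),
                       circ_read_pairs = 400L,
                       read_length = 75L, n_read_pairs = 50000L,
                       fragment_mean = 170, fragment_sd = 25,
                       error_rate = 0,
                       circ_fraction_loading = c(0.16, 0.13, 0.10, 0.08,
                                                 0.05, 0.03, 0.02, 0.01),
                       linear_fraction_loading = c(0.04, 0.05, 0.06, 0.08,
                                                   0.10, 0.12, 0.14, 0.16),
                       fraction_read_pairs = 12000L,
                       netseq_gene_rate = 0.5,
                       netseq_exon_factor = 3,
                       netseq_intron_factor = 1,
                       netseq_stall_height = 4,
                       netseq_stall_width = 5,
                       netseq_accel = 0,
                       netseq_circ_exon_factor = NULL,
                       netseq_circ_intron_factor = NULL) {
  cfg <- as.list(environment())
  if (abs(sum(circ_acceptor_bias) - 1) > 1e-6)
    stop("circ_acceptor_bias must sum to 1")
  if (abs(sum(circ_span_dist) - 1) > 1e-6)
    stop("circ_span_dist must sum to 1")
  if (sum(circ_fraction_loading) > 1 + 1e-9 ||
      sum(linear_fraction_loading) > 1 + 1e-9)
    stop("fraction loading masses must sum to <= 1 (residue = free pool)")
  if (length(circ_fraction_loading) != 8L ||
      length(linear_fraction_loading) != 8L)
    stop("fraction loading models need exactly 8 fractions")
  if (n_circ_genes > n_genes) stop("n_circ_genes > n_genes")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  structure(cfg, class = "sim_config")
}

.sample_weighted <- function(dist, n) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy genome, annotation and planted-circRNA truth set
#'
#' Genes are laid out non-overlapping on a single chromosome, strands
#' alternating. CircRNA-designated genes receive an acceptor ordinal and
#' exon span drawn from the configured biases, and the two introns
#' flanking the circle are inflated by `circ_flank_intron_factor`.
#'
#' @param config a [sim_config()].
#' @return list of class `circ_sim`: `genome` (DNAStringSet), `exons`
#'   (exon table, one isoform per gene), `truth` (one row per planted
#'   circRNA: gene, transcript_id, ordinals, genomic span, junction key,
#'   circle length, planted pairs), `linear_weight` (relative linear
#'   abundance per gene) and `config`.
#' @export
generate_genome_annotation <- function(config = sim_config()) {
  cfg <- config
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  if (n == 0L) {
    return(structure(list(genome = Biostrings::DNAStringSet(),
                          exons = empty_exon_table(),
                          truth = .empty_truth(), linear_weight = numeric(),
                          config = cfg), class = "circ_sim"))
  }
  circ_idx <- sort(sample.int(n, cfg$n_circ_genes))
  genes <- sprintf("G%03d", seq_len(n))
  strands <- rep(c("+", "-"), length.out = n)
  cursor <- 200L
  chrom <- "chrS1"
  exon_rows <- vector("list", n)
  truth_rows <- list()
  for (i in seq_len(n)) {
    is_circ <- i %in% circ_idx
    n_ex <- cfg$exon_count_min +
      stats::rpois(1, max(cfg$exon_count_mean - cfg$exon_count_min, 0))
    acc <- don <- NA_integer_
    if (is_circ) {
      acc <- .sample_weighted(cfg$circ_acceptor_bias, 1)
      don <- acc + .sample_weighted(cfg$circ_span_dist, 1) - 1L
      # both flanking introns must exist: acceptor >= 2, donor <= n_ex - 1
      n_ex <- max(n_ex, don + 1L)
    }
    ex_len <- integer(n_ex)
    ex_len[c(1, n_ex)] <- pmax(40L, round(stats::rlnorm(
      2, cfg$terminal_exon_meanlog, cfg$terminal_exon_sdlog)))
    if (n_ex > 2)
      ex_len[2:(n_ex - 1)] <- pmax(40L, round(stats::rlnorm(
        n_ex - 2, cfg$internal_exon_meanlog, cfg$internal_exon_sdlog)))
    if (any(ex_len <= 0)) stop("exon length model produced non-positive length")
    in_len <- pmax(60L, round(stats::rlnorm(
      n_ex - 1, cfg$intron_meanlog, cfg$intron_sdlog)))
    in_len[1] <- in_len[1] * cfg$first_intron_factor
    if (is_circ) {
      flanks <- c(acc - 1L, don)          # transcription-order intron ordinals
      in_len[flanks] <- in_len[flanks] * cfg$circ_flank_intron_factor
    }
    if (any(in_len <= 0)) stop("intron length model produced non-positive length")
    # transcription-order feature lengths -> genomic layout
    feat_len <- integer(2 * n_ex - 1)
    feat_len[seq(1, 2 * n_ex - 1, 2)] <- ex_len
    feat_len[seq(2, 2 * n_ex - 2, 2)] <- in_len
    if (strands[i] == "-") feat_len <- rev(feat_len)
    offs <- cumsum(c(0L, head(feat_len, -1L)))
    ex_slots <- seq(1, 2 * n_ex - 1, 2)
    g_start <- cursor + offs[ex_slots]
    g_end <- g_start + feat_len[ex_slots]
    ordinals <- if (strands[i] == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    exon_rows[[i]] <- data.table(
      gene = genes[i], transcript_id = paste0(genes[i], ".t1"),
      chrom = chrom, strand = strands[i],
      tx_start = cursor, tx_end = cursor + sum(feat_len),
      exon_idx = seq_len(n_ex), start = as.integer(g_start),
      end = as.integer(g_end), ordinal = ordinals)
    if (is_circ) {
      e <- exon_rows[[i]]
      circ_ex <- e[ordinal >= acc & ordinal <= don]
      truth_rows[[length(truth_rows) + 1L]] <- data.table(
        gene = genes[i], transcript_id = paste0(genes[i], ".t1"),
        chrom = chrom, strand = strands[i],
        acceptor_ordinal = acc, donor_ordinal = don,
        circ_start = min(circ_ex$start), circ_end = max(circ_ex$end),
        circle_len = sum(circ_ex$end - circ_ex$start),
        planted_pairs = as.integer(cfg$circ_read_pairs))
    }
    cursor <- cursor + sum(feat_len) + 300L
  }
  exons <- rbindlist(exon_rows)
  truth <- if (length(truth_rows)) rbindlist(truth_rows) else .empty_truth()
  if (nrow(truth))
    truth[, key := paste(chrom, circ_start, circ_end, strand, sep = ":")]
  genome <- Biostrings::DNAStringSet(
    setNames(.random_dna(cursor + 200L), chrom))
  linear_weight <- setNames(stats::rlnorm(n, 0, 0.8), genes)
  structure(list(genome = genome, exons = exons, truth = truth,
                 linear_weight = linear_weight, config = cfg),
            class = "circ_sim")
}

.empty_truth <- function() {
  dtab(gene = character(), transcript_id = character(),
             chrom = character(), strand = character(),
             acceptor_ordinal = integer(), donor_ordinal = integer(),
             circ_start = integer(), circ_end = integer(),
             circle_len = integer(), planted_pairs = integer(),
             key = character())
}

#' Spliced circular sequence of a planted circRNA
#' @param sim a `circ_sim`.
#' @param truth_row one row of `sim$truth`.
#' @return character scalar: exons acceptor..donor joined, transcription
#'   orientation; the back-splice junction is the wrap between the last
#'   and first nucleotide.
#' @export
circle_sequence <- function(sim, truth_row) {
  e <- sim$exons[transcript_id == truth_row$transcript_id &
                   ordinal >= truth_row$acceptor_ordinal &
                   ordinal <= truth_row$donor_ordinal]
  paste(exon_sequences_tx(e, sim$genome), collapse = "")
}

# draw n read pairs from one molecule; circular molecules wrap at the end
.gen_pairs_one <- function(seq, n, circular, cfg) {
  L <- nchar(seq)
  rl <- cfg$read_length
  if (n == 0L || L < rl)
    return(list(r1 = character(0), r2 = character(0),
                j1 = logical(0), j2 = logical(0)))
  frag <- pmin(pmax(round(stats::rnorm(n, cfg$fragment_mean,
                                       cfg$fragment_sd)), rl), L)
  if (circular) {
    s <- sample.int(L, n, replace = TRUE)
    ss <- paste0(seq, seq)
    r1 <- substring(ss, s, s + rl - 1L)
    e2s <- s + frag - rl
    r2f <- substring(ss, e2s, s + frag - 1L)
    j1 <- (s + rl - 1L) > L
    j2 <- e2s <= L & (s + frag - 1L) > L
  } else {
    s <- 1L + floor(stats::runif(n) * (L - frag + 1L))  # frag is a vector
    r1 <- substring(seq, s, s + rl - 1L)
    r2f <- substring(seq, s + frag - rl, s + frag - 1L)
    j1 <- j2 <- rep(FALSE, n)
  }
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r2f)))
  list(r1 = r1, r2 = r2, j1 = j1, j2 = j2)
}

.apply_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  rl <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), rl, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    p <- sample.int(rl, n_err[i])
    ch <- strsplit(reads[i], "")[[1]]
    ch[p] <- sample(c("A", "C", "G", "T"), n_err[i], replace = TRUE)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate a paired-end read library
#'
#' Linear pairs follow annotated splicing; circRNA pairs are drawn from
#' the circular spliced sequence, so junction-crossing reads arise
#' naturally when a fragment spans the wrap point. Read IDs carry the
#' ground-truth class (`lin`/`circ`), origin and per-read
#' junction-crossing flags, so detector output can be scored without
#' alignment.
#'
#' @param sim a `circ_sim` from [generate_genome_annotation()].
#' @param n_read_pairs total pairs (default `config$n_read_pairs`).
#' @param seed_offset offset added to the master seed for this library's
#'   RNG stream.
#' @return list: `read1`, `read2` (named DNAStringSets), `mapped_reads`
#'   (total reads, 2 per pair), `truth` (data.table read_id, truth_class,
#'   origin, j1, j2).
#' @export
simulate_read_pairs <- function(sim, n_read_pairs = NULL,
                                seed_offset = 101L) {
  cfg <- sim$config
  if (is.null(n_read_pairs)) n_read_pairs <- cfg$n_read_pairs
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + seed_offset)
  tx_seqs <- as.character(transcript_sequences(sim$exons, sim$genome))
  tx_of_gene <- setNames(names(tx_seqs),
                         sub("\\.t1$", "", names(tx_seqs)))
  n_circ_pairs <- if (nrow(sim$truth)) sum(sim$truth$planted_pairs) else 0L
  too_short <- if (nrow(sim$truth))
    sim$truth$circle_len < cfg$read_length else logical(0)
  if (any(too_short)) {
    warning("skipping ", sum(too_short),
            " planted circRNA(s) shorter than the read length")
    n_circ_pairs <- sum(sim$truth$planted_pairs[!too_short])
  }
  n_lin <- max(n_read_pairs - n_circ_pairs, 0L)
  w <- sim$linear_weight
  lin_alloc <- if (n_lin > 0 && length(w))
    as.integer(stats::rmultinom(1, n_lin, w)) else integer(length(w))
  r1 <- r2 <- ids <- character(0)
  cls <- org <- character(0); jf1 <- jf2 <- logical(0)
  for (i in seq_along(w)) {
    if (lin_alloc[i] == 0L) next
    g <- names(w)[i]
    pp <- .gen_pairs_one(tx_seqs[[tx_of_gene[[g]]]], lin_alloc[i], FALSE, cfg)
    r1 <- c(r1, pp$r1); r2 <- c(r2, pp$r2)
    cls <- c(cls, rep("lin", lin_alloc[i]))
    org <- c(org, rep(g, lin_alloc[i]))
    jf1 <- c(jf1, pp$j1); jf2 <- c(jf2, pp$j2)
  }
  if (nrow(sim$truth)) {
    for (i in seq_len(nrow(sim$truth))) {
      if (too_short[i]) next
      tr <- sim$truth[i]
      pp <- .gen_pairs_one(circle_sequence(sim, tr), tr$planted_pairs,
                           TRUE, cfg)
      r1 <- c(r1, pp$r1); r2 <- c(r2, pp$r2)
      cls <- c(cls, rep("circ", length(pp$r1)))
      org <- c(org, rep(tr$key, length(pp$r1)))
      jf1 <- c(jf1, pp$j1); jf2 <- c(jf2, pp$j2)
    }
  }
  r1 <- .apply_errors(r1, cfg$error_rate)
  r2 <- .apply_errors(r2, cfg$error_rate)
  ids <- sprintf("rp%06d|%s|%s|%d%d", seq_along(r1), cls, org,
                 as.integer(jf1), as.integer(jf2))
  list(read1 = Biostrings::DNAStringSet(setNames(r1, ids)),
       read2 = Biostrings::DNAStringSet(setNames(r2, ids)),
       mapped_reads = 2L * length(r1),
       truth = data.table(read_id = ids, truth_class = cls, origin = org,
                          j1 = jf1, j2 = jf2))
}

#' Simulate the nine sedimentation libraries (total + fractions 1..8)
#'
#' Each molecule class has a loading model: the probability of a read
#' landing in ribosomal fractions 1..8, with the residue forming the free
#' pool. The total-cytoplasmic library samples all molecules regardless of
#' loading; each fraction library samples molecules proportionally to
#' abundance x loading. Short circRNAs can be made to load low fractions
#' more by supplying a loading vector concentrated there.
#'
#' @param sim a `circ_sim`.
#' @param circ_loading,linear_loading 8-element loading vectors (default
#'   from config).
#' @param pairs_per_set read pairs per library (default from config).
#' @return named list `total`, `f1`..`f8`, each as in
#'   [simulate_read_pairs()].
#' @export
simulate_fractions <- function(sim, circ_loading = NULL,
                               linear_loading = NULL,
                               pairs_per_set = NULL) {
  cfg <- sim$config
  if (is.null(circ_loading)) circ_loading <- cfg$circ_fraction_loading
  if (is.null(linear_loading)) linear_loading <- cfg$linear_fraction_loading
  if (is.null(pairs_per_set)) pairs_per_set <- cfg$fraction_read_pairs
  if (sum(circ_loading) > 1 + 1e-9 || sum(linear_loading) > 1 + 1e-9)
    stop("loading must sum to <= 1 per molecule class")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 202L)
  tx_seqs <- as.character(transcript_sequences(sim$exons, sim$genome))
  mol <- data.table(
    id = names(tx_seqs), class_ = "lin",
    seq = unname(tx_seqs),
    weight = unname(sim$linear_weight[sub("\\.t1$", "", names(tx_seqs))]))
  if (nrow(sim$truth)) {
    circ_seqs <- vapply(seq_len(nrow(sim$truth)),
                        function(i) circle_sequence(sim, sim$truth[i]),
                        character(1))
    mol <- rbind(mol, data.table(
      id = sim$truth$key, class_ = "circ", seq = circ_seqs,
      weight = sim$truth$planted_pairs / max(sum(sim$truth$planted_pairs), 1) *
        sum(sim$linear_weight) * 0.2))
  }
  gen_set <- function(weights, label) {
    if (sum(weights) <= 0) {
      alloc <- integer(nrow(mol))
    } else alloc <- as.integer(stats::rmultinom(1, pairs_per_set, weights))
    r1 <- r2 <- character(0); cls <- org <- character(0)
    jf1 <- jf2 <- logical(0)
    for (i in seq_len(nrow(mol))) {
      if (alloc[i] == 0L) next
      pp <- .gen_pairs_one(mol$seq[i], alloc[i], mol$class_[i] == "circ", cfg)
      r1 <- c(r1, pp$r1); r2 <- c(r2, pp$r2)
      cls <- c(cls, rep(mol$class_[i], length(pp$r1)))
      org <- c(org, rep(mol$id[i], length(pp$r1)))
      jf1 <- c(jf1, pp$j1); jf2 <- c(jf2, pp$j2)
    }
    ids <- sprintf("%s:rp%06d|%s|%s|%d%d", label, seq_along(r1), cls, org,
                   as.integer(jf1), as.integer(jf2))
    list(read1 = Biostrings::DNAStringSet(setNames(r1, ids)),
         read2 = Biostrings::DNAStringSet(setNames(r2, ids)),
         mapped_reads = 2L * length(r1),
         truth = data.table(read_id = ids, truth_class = cls, origin = org,
                            j1 = jf1, j2 = jf2))
  }
  out <- vector("list", 9L)
  names(out) <- c("total", paste0("f", 1:8))
  out[["total"]] <- gen_set(mol$weight, "total")
  for (f in 1:8) {
    lw <- ifelse(mol$class_ == "circ", circ_loading[f], linear_loading[f])
    out[[paste0("f", f)]] <- gen_set(mol$weight * lw, paste0("f", f))
  }
  out
}

#' Write a paired read set as FASTQ
#' @param reads list with `read1`, `read2` DNAStringSets.
#' @param prefix output path prefix; writes `<prefix>_1.fastq.gz` and
#'   `<prefix>_2.fastq.gz`.
#' @export
write_read_pairs <- function(reads, prefix) {
  for (m in 1:2) {
    x <- reads[[paste0("read", m)]]
    path <- paste0(prefix, "_", m, ".fastq.gz")
    Biostrings::writeXStringSet(x, path, format = "fastq", compress = TRUE)
  }
  invisible(prefix)
}
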