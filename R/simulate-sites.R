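# Planted regulatory sites: exact miRNA seed matches written into circRNA
# exons (with or without a covering AGO footprint), AGO/RBP footprint
# intervals and m6A sites, so the sponge filter has known positives and
# negatives.

#' Map a transcript-space segment to genomic intervals
#'
#' The transcript space is the concatenation of the supplied exons in
#' transcription order (ordinal ascending). A segment may cross linear
#' splice boundaries and then maps to several genomic pieces.
#'
#' @param exons_sub exon table rows of one transcript (the exons forming
#'   the coordinate space), any order.
#' @param pos 1-based start of the segment on the concatenated sequence.
#' @param len segment length in nt.
#' @return data.table chrom, start, end (0-based half-open), strand,
#'   `piece` (1-based order along the transcript).
#' @export
map_transcript_to_genome <- function(exons_sub, pos, len) {
  e <- as.data.table(exons_sub)[order(ordinal)]
  lens <- e$end - e$start
  offs <- cumsum(c(0L, head(lens, -1L)))
  t0 <- pos - 1L; t1 <- t0 + len      # 0-based half-open in transcript space
  if (t0 < 0 || t1 > sum(lens)) stop("segment outside transcript space")
  pieces <- list()
  for (i in seq_len(nrow(e))) {
    a <- max(t0, offs[i]); b <- min(t1, offs[i] + lens[i])
    if (a >= b) next
    la <- a - offs[i]; lb <- b - offs[i]     # local 0-based within exon
    if (e$strand[i] == "+") {
      gs <- e$start[i] + la; ge <- e$start[i] + lb
    } else {
      gs <- e$end[i] - lb; ge <- e$end[i] - la
    }
    pieces[[length(pieces) + 1L]] <- data.table(
      chrom = e$chrom[i], start = gs, end = ge, strand = e$strand[i],
      piece = length(pieces) + 1L)
  }
  rbindlist(pieces)
}

.random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

.seed_target_dna <- function(mirna) {
  seed <- substr(gsub("U", "T", mirna), 2, 7)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seed)))
}

# write a transcript-space 6-mer into the genome (piecewise, strand-aware)
.plant_target <- function(genome, exons_sub, pos, target) {
  pieces <- map_transcript_to_genome(exons_sub, pos, nchar(target))
  off <- 0L
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i]
    w <- p$end - p$start
    sub <- substr(target, off + 1L, off + w)
    if (p$strand == "-")
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    genome[[p$chrom]] <- Biostrings::replaceAt(
      genome[[p$chrom]], IRanges::IRanges(p$start + 1L, p$end), sub)
    off <- off + w
  }
  genome
}

#' Plant miRNA seed matches, AGO footprints and m6A sites
#'
#' Two of the generated miRNAs are designated as planted: in every
#' sufficiently long planted circle, an exact reverse-complement match to
#' miRNA positions 2-7 of the first is written into the exonic sequence
#' and covered by an AGO footprint (a known filter-positive), and a match
#' to the second is written without AGO cover (a known filter-negative).
#' In the first circle the supported match straddles the back-splice
#' junction (3 nt on each side). Planted seeds are chosen so their target
#' hexamer is absent from all circle sequences beforehand.
#'
#' @param sim a `circ_sim`.
#' @param n_mirnas number of mature miRNA sequences to emit (>= 2).
#' @param ago_background number of additional random AGO footprints placed
#'   in non-circularised exons.
#' @param m6a_per_circ m6A sites planted inside each circle's acceptor
#'   exon.
#' @return list: `sim` (with the mutated genome), `mirnas` (named
#'   character, RNA alphabet), `ago_sites` (data.table protein, chrom,
#'   start, end), `m6a_sites` (single-nt interval table), `site_truth`
#'   (data.table key, mirna, seed_hex, circ_pos, junction_spanning,
#'   ago_supported).
#' @export
simulate_regulatory_sites <- function(sim, n_mirnas = 8L,
                                      ago_background = 10L,
                                      m6a_per_circ = 1L) {
  cfg <- sim$config
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 404L)
  circ_seqs <- if (nrow(sim$truth))
    vapply(seq_len(nrow(sim$truth)),
           function(i) circle_sequence(sim, sim$truth[i]), character(1))
  else character(0)
  mirnas <- character(n_mirnas)
  for (i in seq_len(n_mirnas)) {
    repeat {
      cand <- .random_rna(22L)
      tgt <- .seed_target_dna(cand)
      if (i > 2L ||
          !any(vapply(circ_seqs, function(s)
            grepl(tgt, paste0(s, substr(s, 1, 5)), fixed = TRUE),
            logical(1)))) { mirnas[i] <- cand; break }
    }
  }
  names(mirnas) <- sprintf("mirsim-%02d", seq_len(n_mirnas))
  genome <- sim$genome
  truth_rows <- list(); ago_rows <- list(); m6a_rows <- list()
  tgt1 <- .seed_target_dna(mirnas[1]); tgt2 <- .seed_target_dna(mirnas[2])
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i]
    e <- sim$exons[transcript_id == tr$transcript_id &
                     ordinal >= tr$acceptor_ordinal &
                     ordinal <= tr$donor_ordinal]
    L <- tr$circle_len
    if (L < 90L) next
    junction_site <- i == 1L && L >= 40L
    pos_sup <- if (junction_site) L - 2L else max(floor(L / 3), 9L)
    # supported site: write the target (wrapping for the junction case)
    if (junction_site) {
      genome <- .plant_target(genome, e, pos_sup, substr(tgt1, 1, 3))
      genome <- .plant_target(genome, e, 1L, substr(tgt1, 4, 6))
    } else genome <- .plant_target(genome, e, pos_sup, tgt1)
    # AGO footprint: the genomic extent of the larger arm of the 20-nt
    # predicted target site centred on the seed match
    site_lo <- pos_sup - 7L
    if (junction_site) {
      arm1 <- map_transcript_to_genome(e, site_lo, L - site_lo + 1L)
      arm2 <- map_transcript_to_genome(e, 1L, 20L - (L - site_lo + 1L))
      arm <- rbind(arm1, arm2)[which.max(end - start)]
    } else {
      pcs <- map_transcript_to_genome(e, max(site_lo, 1L), 20L)
      arm <- pcs[which.max(end - start)]
    }
    ago_rows[[length(ago_rows) + 1L]] <- data.table(
      protein = "AGO2", chrom = arm$chrom, start = arm$start,
      end = arm$end)
    truth_rows[[length(truth_rows) + 1L]] <- dtab(
      key = tr$key, mirna = names(mirnas)[1],
      seed_hex = substr(mirnas[1], 2, 7), circ_pos = pos_sup,
      junction_spanning = junction_site, ago_supported = TRUE)
    # unsupported site: far from the AGO footprint, no cover
    pos_un <- max(floor(2 * L / 3), pos_sup %% L + 40L)
    if (pos_un + 5L <= L - 5L && abs(pos_un - pos_sup) > 40L) {
      genome <- .plant_target(genome, e, pos_un, tgt2)
      truth_rows[[length(truth_rows) + 1L]] <- dtab(
        key = tr$key, mirna = names(mirnas)[2],
        seed_hex = substr(mirnas[2], 2, 7), circ_pos = pos_un,
        junction_spanning = FALSE, ago_supported = FALSE)
    }
    if (m6a_per_circ > 0L) {
      acc_exon <- e[ordinal == tr$acceptor_ordinal]
      p <- acc_exon$start + sample.int(acc_exon$end - acc_exon$start,
                                       m6a_per_circ)
      m6a_rows[[length(m6a_rows) + 1L]] <- data.table(
        chrom = acc_exon$chrom, start = p - 1L, end = p)
    }
  }
  # background AGO footprints in non-circularised exons
  circ_tx <- unique(sim$truth$transcript_id)
  bg_pool <- sim$exons[!transcript_id %in% circ_tx & end - start >= 40L]
  if (nrow(bg_pool) && ago_background > 0L) {
    picks <- bg_pool[sample.int(.N, min(ago_background, .N))]
    s <- picks$start + vapply(picks$end - picks$start - 20L,
                              function(m) sample.int(max(m, 1L), 1L),
                              integer(1))
    ago_rows[[length(ago_rows) + 1L]] <- data.table(
      protein = "AGO2", chrom = picks$chrom, start = s, end = s + 20L)
  }
  ago_sites <- if (length(ago_rows)) rbindlist(ago_rows, use.names = TRUE)
    else data.table(protein = character(), chrom = character(),
                    start = integer(), end = integer())
  m6a_sites <- if (length(m6a_rows)) unique(rbindlist(m6a_rows))
    else data.table(chrom = character(), start = integer(), end = integer())
  sim$genome <- genome
  list(sim = sim, mirnas = mirnas, ago_sites = ago_sites,
       m6a_sites = m6a_sites,
       site_truth = if (length(truth_rows)) rbindlist(truth_rows)
         else dtab(key = character(), mirna = character(),
                         seed_hex = character(), circ_pos = integer(),
                         junction_spanning = logical(),
                         ago_supported = logical()))
}
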