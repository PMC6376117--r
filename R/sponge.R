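# miRNA sponge scoring: exact seed matches (miRNA positions 2-7,
# Watson-Crick only) over the circular spliced sequence including the
# junction wrap, filtered by AGO footprint support, summarised per circRNA
# and per seed.

#' Scan a circular sequence for miRNA seed matches
#'
#' Finds every position where the 6-nt reverse complement of a miRNA's
#' seed (positions 2-7 from the 5' end) occurs in the circle's spliced
#' sequence, including matches crossing the back-splice junction (the
#' first 5 nt are appended for the wrap scan). G:U pairing is not
#' allowed. Overlapping matches are reported at their distinct start
#' positions.
#'
#' @param mirnas named character vector of mature miRNA sequences
#'   (RNA or DNA alphabet); entries shorter than 7 nt are skipped with a
#'   warning.
#' @param circ_seq character scalar: circular spliced sequence (DNA
#'   alphabet; RNA accepted).
#' @return data.table mirna, seed_hex (RNA alphabet, positions 2-7), pos
#'   (1-based start on the circle), junction_spanning.
#' @export
scan_seed_matches <- function(mirnas, circ_seq) {
  s <- toupper(gsub("U", "T", as.character(circ_seq)))
  L <- nchar(s)
  wrapped <- Biostrings::DNAString(paste0(s, substr(s, 1L, 5L)))
  short <- nchar(mirnas) < 7L
  if (any(short)) {
    warning("skipping ", sum(short), " miRNA(s) shorter than 7 nt")
    mirnas <- mirnas[!short]
  }
  rows <- list()
  for (nm in names(mirnas)) {
    seed_rna <- substr(gsub("T", "U", toupper(mirnas[[nm]])), 2, 7)
    target <- Biostrings::reverseComplement(
      Biostrings::DNAString(gsub("U", "T", seed_rna)))
    m <- Biostrings::matchPattern(target, wrapped)
    starts <- BiocGenerics::start(m)
    starts <- starts[starts <= L]
    if (length(starts))
      rows[[length(rows) + 1L]] <- data.table(
        mirna = nm, seed_hex = seed_rna, pos = starts,
        junction_spanning = (starts + 5L) > L)
  }
  if (!length(rows))
    return(data.table(mirna = character(), seed_hex = character(),
                      pos = integer(), junction_spanning = logical()))
  rbindlist(rows)
}

#' AGO-support filter for seed matches
#'
#' The predicted target site is the ~20-nt hybrid region centred on the
#' 6-nt seed match (7 nt flank either side by default). It is supported
#' iff at least `min_fraction` of it overlaps an AGO footprint extended
#' by `extension` nt up- and downstream. Junction-spanning sites are
#' evaluated on each genomic arm and scored by the maximal arm overlap;
#' sites crossing linear splice boundaries sum their pieces' overlaps.
#'
#' @param matches output of [scan_seed_matches()].
#' @param circ_exons exon table rows forming the circle (transcription
#'   order determined by `ordinal`).
#' @param ago_sites interval table of AGO footprints.
#' @param extension nt added on both sides of each AGO site (default 10).
#' @param min_fraction required overlap fraction of the site (default
#'   0.5, inclusive).
#' @param site_flank nt either side of the seed match forming the site
#'   (default 7, giving a 20-nt site).
#' @return `matches` with an `ago_supported` logical column.
#' @export
filter_by_ago <- function(matches, circ_exons, ago_sites, extension = 10L,
                          min_fraction = 0.5, site_flank = 7L) {
  matches <- as.data.table(matches)
  if (!nrow(matches)) {
    matches[, ago_supported := logical(0)]
    return(matches)
  }
  e <- as.data.table(circ_exons)[order(ordinal)]
  L <- sum(e$end - e$start)
  ago <- as.data.table(ago_sites)
  ext <- if (nrow(ago))
    GenomicRanges::reduce(intervals_to_granges(
      ago[, .(chrom, start = pmax(start - extension, 0L),
              end = end + extension)], keep_strand = FALSE))
  else GenomicRanges::GRanges()
  site_w <- 6L + 2L * site_flank
  supported <- logical(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    lo <- matches$pos[i] - site_flank          # 1-based, may underflow/wrap
    segs <- data.table(a = ((lo - 1L) %% L) + 1L, len = site_w)
    # split at the junction wrap into arms
    arms <- list()
    a <- segs$a; remaining <- segs$len
    while (remaining > 0L) {
      take <- min(remaining, L - a + 1L)
      arms[[length(arms) + 1L]] <- c(a, take)
      remaining <- remaining - take
      a <- 1L
    }
    wraps <- length(arms) > 1L
    arm_ov <- vapply(arms, function(ar) {
      pieces <- map_transcript_to_genome(e, ar[1], ar[2])
      if (!nrow(pieces) || !length(ext)) return(0L)
      hits <- GenomicRanges::findOverlaps(
        intervals_to_granges(pieces, keep_strand = FALSE), ext,
        ignore.strand = TRUE)
      if (!length(hits)) return(0L)
      sum(GenomicRanges::width(GenomicRanges::pintersect(
        intervals_to_granges(pieces,
                             keep_strand = FALSE)[S4Vectors::queryHits(hits)],
        ext[S4Vectors::subjectHits(hits)])))
    }, integer(1))
    ov <- if (wraps) max(arm_ov) else sum(arm_ov)
    supported[i] <- ov >= min_fraction * site_w
  }
  matches[, ago_supported := supported]
  matches[]
}

#' Sponge summaries across a circRNA set
#'
#' @param matches data.table with columns circ (junction key), mirna,
#'   seed_hex, pos and ago_supported (typically rbind of per-circ
#'   [filter_by_ago()] outputs with a `circ` column added).
#' @param occurrence_threshold report seeds present in at least this many
#'   circRNAs (default 8).
#' @param supported_only count only AGO-supported matches (default TRUE).
#' @return list: `per_circ` (circ, n_sites: distinct supported positions),
#'   `per_seed` (seed_hex, n_circ: distinct circRNAs with >= 1 site),
#'   `collective` (per_seed rows at/above the occurrence threshold).
#' @export
sponge_summary <- function(matches, occurrence_threshold = 8L,
                           supported_only = TRUE) {
  m <- as.data.table(matches)
  if (supported_only && "ago_supported" %in% names(m))
    m <- m[ago_supported == TRUE]
  per_circ <- m[, .(n_sites = uniqueN(pos)), by = circ]
  per_seed <- m[, .(n_circ = uniqueN(circ)), by = seed_hex]
  list(per_circ = per_circ[order(-n_sites)],
       per_seed = per_seed[order(-n_circ)],
       collective = per_seed[n_circ >= occurrence_threshold][order(-n_circ)])
}

#' RBP footprint density comparison between exon classes
#'
#' A footprint is assigned to an exon class (circularised vs
#' non-circularised) iff at least `min_fraction` of the site overlaps an
#' exon of that class. Per protein, the proportion of exons bearing at
#' least one footprint is compared between classes with a two-sample
#' proportion test.
#'
#' @param sites data.table protein, chrom, start, end.
#' @param circ_exons,noncirc_exons interval tables of the two exon
#'   classes.
#' @param min_fraction required site-overlap fraction (default 0.75).
#' @return data.table protein, n_sites_circ, n_sites_noncirc,
#'   prop_exons_circ, prop_exons_noncirc, p, direction ("circ",
#'   "noncirc" or "equal"); proteins with zero sites are skipped with a
#'   warning.
#' @export
rbp_footprint_comparison <- function(sites, circ_exons, noncirc_exons,
                                     min_fraction = 0.75) {
  sites <- as.data.table(sites)
  circ_exons <- as.data.table(circ_exons)
  noncirc_exons <- as.data.table(noncirc_exons)
  out <- list()
  for (pr in unique(sites$protein)) {
    ps <- sites[protein == pr]
    if (!nrow(ps)) { warning("no sites for protein ", pr); next }
    ov_c <- intersect_intervals(ps, circ_exons, min_fraction)
    ov_n <- intersect_intervals(ps, noncirc_exons, min_fraction)
    bearing_c <- length(unique(ov_c$sidx))
    bearing_n <- length(unique(ov_n$sidx))
    pt <- proportion_test(bearing_c, nrow(circ_exons),
                          bearing_n, nrow(noncirc_exons))
    out[[pr]] <- data.table(
      protein = pr, n_sites_circ = length(unique(ov_c$qidx)),
      n_sites_noncirc = length(unique(ov_n$qidx)),
      prop_exons_circ = pt$prop1, prop_exons_noncirc = pt$prop2,
      p = pt$p,
      direction = switch(pt$direction, group1 = "circ",
                         group2 = "noncirc", "equal"))
  }
  if (!length(out))
    return(data.table(protein = character(), n_sites_circ = integer(),
                      n_sites_noncirc = integer(),
                      prop_exons_circ = numeric(),
                      prop_exons_noncirc = numeric(), p = numeric(),
                      direction = character()))
  rbindlist(out)
}
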