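# Structural statistics of circRNA-producing loci: positional profiles
# normalised to exon frequency, exon-span histograms, exon/intron length
# tables with rank-sum tests, and isoform diversity.

#' Exon counts by ordinal position across a transcript set
#'
#' An exon exists at ordinal position N for every transcript with at
#' least N exons, so the counts decline as mRNA prevalence declines with
#' exon number.
#'
#' @param exons exon table (the gene set of interest).
#' @return data.table position, count.
#' @export
exon_position_frequency <- function(exons) {
  exons <- as.data.table(exons)
  if (!nrow(exons))
    return(data.table(position = integer(), count = integer()))
  exons[, .(count = .N), by = .(position = ordinal)][order(position)]
}

#' Back-splice position profile normalised to exon frequency
#'
#' For each ordinal position, the acceptor (or donor) count is divided by
#' the number of exons existing at that position, and the resulting
#' ratios are rescaled to sum to 1 over the occupied positions. Positions
#' with zero exon count are excluded.
#'
#' @param ordinals integer vector of acceptor (or donor) ordinal
#'   positions, one entry per (circRNA, isoform) pair (the inclusive
#'   isoform assignment).
#' @param exon_freq output of [exon_position_frequency()].
#' @return data.table position, count, exon_count, ratio, frequency
#'   (frequencies sum to 1).
#' @export
backsplice_position_profile <- function(ordinals, exon_freq) {
  ef <- as.data.table(exon_freq)[count > 0]
  setnames(ef, "count", "exon_count")
  cnt <- data.table(position = as.integer(ordinals))[, .(count = .N),
                                                     by = position]
  prof <- merge(ef, cnt, by = "position", all.x = TRUE)
  prof[is.na(count), count := 0L]
  prof[, ratio := count / exon_count]
  if (all(prof$ratio == 0)) stop("all position ratios are zero")
  prof[, frequency := ratio / sum(ratio)]
  prof[order(position), .(position, count, exon_count, ratio, frequency)]
}

#' CircRNA exon-span histogram
#'
#' Span = donor ordinal - acceptor ordinal + 1 (1 = single-exon circRNA).
#'
#' @param circ data.table with acceptor_ordinal and donor_ordinal.
#' @return data.table span, count.
#' @export
circ_exon_span_distribution <- function(circ) {
  circ <- as.data.table(circ)
  circ[, .(count = .N),
       by = .(span = donor_ordinal - acceptor_ordinal + 1L)][order(span)]
}

#' Cognate linear isoforms of each circRNA (inclusive assignment)
#'
#' Every annotated isoform whose exons fully cover the circle span is a
#' potential cognate linear isoform: the isoform must contain exons whose
#' genomic extent covers [circ_start, circ_end) with exon boundaries
#' matching the circle ends.
#'
#' @param circ data.table key, chrom, strand, circ_start, circ_end.
#' @param exons exon table.
#' @return data.table key, transcript_id, acceptor_ordinal, donor_ordinal
#'   (the ordinals of the circle-end exons in that isoform).
#' @export
cognate_isoforms <- function(circ, exons) {
  circ <- as.data.table(circ); exons <- as.data.table(exons)
  rows <- list()
  for (i in seq_len(nrow(circ))) {
    cr <- circ[i]
    cand <- exons[chrom == cr$chrom & strand == cr$strand &
                    tx_start <= cr$circ_start & tx_end >= cr$circ_end]
    for (tx in unique(cand$transcript_id)) {
      e <- cand[transcript_id == tx]
      first <- e[start == cr$circ_start]
      last <- e[end == cr$circ_end]
      if (!nrow(first) || !nrow(last)) next
      ords <- sort(c(first$ordinal[1], last$ordinal[1]))
      rows[[length(rows) + 1L]] <- dtab(
        key = cr$key, transcript_id = tx,
        acceptor_ordinal = ords[1], donor_ordinal = ords[2])
    }
  }
  if (!length(rows))
    return(dtab(key = character(), transcript_id = character(),
                      acceptor_ordinal = integer(),
                      donor_ordinal = integer()))
  rbindlist(rows)
}

#' Exon and intron features of circRNAs under inclusive isoform
#' assignment
#'
#' For each (circRNA, cognate isoform) pair: the acceptor and donor
#' exons, circle-internal exons/introns, and the flanking introns (the
#' intron immediately upstream of the acceptor exon and immediately
#' downstream of the donor exon, transcription order). Single-exon
#' circles contribute their exon as both acceptor and donor.
#'
#' @param circ_iso output of [cognate_isoforms()] (or any table with key,
#'   transcript_id, acceptor_ordinal, donor_ordinal).
#' @param exons exon table.
#' @return data.table key, transcript_id, class_ ("single_exon" or
#'   "multi_exon"), kind ("exon"/"intron"), role
#'   ("acceptor"/"internal"/"donor"/"flank_upstream"/"flank_downstream"),
#'   ordinal, len.
#' @export
circ_features <- function(circ_iso, exons) {
  circ_iso <- as.data.table(circ_iso)
  exons <- as.data.table(exons)
  introns <- derive_introns(exons)
  rows <- list()
  for (i in seq_len(nrow(circ_iso))) {
    ci <- circ_iso[i]
    e <- exons[transcript_id == ci$transcript_id]
    itx <- introns[transcript_id == ci$transcript_id]
    a <- ci$acceptor_ordinal; d <- ci$donor_ordinal
    cls <- if (a == d) "single_exon" else "multi_exon"
    add <- function(kind, role, ord, lo, hi)
      dtab(key = ci$key, transcript_id = ci$transcript_id,
                 class_ = cls, kind = kind, role = role, ordinal = ord,
                 len = hi - lo)
    acc_e <- e[ordinal == a]; don_e <- e[ordinal == d]
    rows[[length(rows) + 1L]] <- add("exon", "acceptor", a,
                                     acc_e$start, acc_e$end)
    if (d > a)
      rows[[length(rows) + 1L]] <- add("exon", "donor", d,
                                       don_e$start, don_e$end)
    if (d - a > 1L) for (o in (a + 1L):(d - 1L)) {
      ie <- e[ordinal == o]
      rows[[length(rows) + 1L]] <- add("exon", "internal", o,
                                       ie$start, ie$end)
    }
    up <- itx[ordinal == a - 1L]          # upstream flank = intron a-1
    if (nrow(up))
      rows[[length(rows) + 1L]] <- add("intron", "flank_upstream", a - 1L,
                                       up$start, up$end)
    dn <- itx[ordinal == d]               # downstream flank = intron d
    if (nrow(dn))
      rows[[length(rows) + 1L]] <- add("intron", "flank_downstream", d,
                                       dn$start, dn$end)
    if (d > a) for (o in a:(d - 1L)) {
      ii <- itx[ordinal == o]
      if (nrow(ii))
        rows[[length(rows) + 1L]] <- add("intron", "internal", o,
                                         ii$start, ii$end)
    }
  }
  if (!length(rows))
    return(dtab(key = character(), transcript_id = character(),
                      class_ = character(), kind = character(),
                      role = character(), ordinal = integer(),
                      len = integer()))
  rbindlist(rows)
}

#' Length table with rank-sum tests against reference features
#'
#' Per (molecule class, feature kind, role): n, mean and median length,
#' and a two-sided Mann-Whitney P value against the matching reference
#' distribution (internal exons of expressed genes for exon rows,
#' reference introns for intron rows; first and last exons removed from
#' the reference, as for typical internal-exon baselines).
#'
#' @param feats output of [circ_features()].
#' @param ref_exons exon table of the reference gene set.
#' @return data.table class_, kind, role, n, mean, median, p, direction
#'   ("circ" when the circ sample has the larger median).
#' @export
length_stats <- function(feats, ref_exons) {
  feats <- as.data.table(feats)
  ref_exons <- as.data.table(ref_exons)
  ref_internal <- ref_exons[, if (.N > 2L) .SD[ordinal > 1L &
                                                 ordinal < max(ordinal)],
                            by = transcript_id]
  ref_ex_len <- ref_internal[, end - start]
  ref_in_len <- derive_introns(ref_exons)[, end - start]
  out <- feats[, {
    ref <- if (kind[1] == "exon") ref_ex_len else ref_in_len
    mw <- mann_whitney_u(len, ref)
    .(n = .N, mean = mean(len), median = as.numeric(stats::median(len)),
      p = mw$p,
      direction = switch(mw$direction, x = "circ", y = "reference",
                         "equal"))
  }, by = .(class_, kind, role)]
  out[order(class_, kind, role)]
}

#' Isoform diversity of gene sets
#'
#' Per-gene count of annotated mRNA isoforms, optionally adding the
#' gene's distinct circRNAs as additional transcript isoforms, compared
#' between the circRNA-producing genes and a reference gene set with a
#' Mann-Whitney test.
#'
#' @param exons exon table (full annotation).
#' @param circ data.table with `gene` and `key` columns (detected
#'   circRNAs).
#' @param reference_genes character vector of reference gene symbols.
#' @param include_circ_as_isoform count circRNAs as isoforms of their
#'   gene (default FALSE).
#' @return list: `per_gene` (gene, n_isoforms for circ genes), `reference`
#'   (same for the reference set), `test` ([mann_whitney_u()] result).
#' @export
isoform_diversity <- function(exons, circ, reference_genes,
                              include_circ_as_isoform = FALSE) {
  exons <- as.data.table(exons); circ <- as.data.table(circ)
  iso <- exons[, .(n_isoforms = uniqueN(transcript_id)), by = gene]
  circ_counts <- circ[, .(n_circ = uniqueN(key)), by = gene]
  circ_genes <- circ_counts$gene
  per_gene <- merge(iso[gene %in% circ_genes], circ_counts, by = "gene")
  if (include_circ_as_isoform)
    per_gene[, n_isoforms := n_isoforms + n_circ]
  ref <- iso[gene %in% reference_genes]
  test <- mann_whitney_u(per_gene$n_isoforms, ref$n_isoforms)
  list(per_gene = per_gene[, .(gene, n_isoforms)],
       reference = ref, test = test)
}
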