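# Gene models live in a flat exon table: one row per exon with the
# transcript context repeated. Columns:
#   gene, transcript_id, chrom, strand, tx_start, tx_end,
#   exon_idx  (1-based index in genomic order),
#   start,end (0-based half-open genomic coordinates),
#   ordinal   (1 = 5'-most exon in transcription direction).
# On the minus strand the right-most exon has ordinal 1.

#' Read gene models from a RefFlat file
#'
#' RefFlat is the UCSC flat annotation format: tab-delimited columns
#' geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds (comma-terminated lists). Coordinates
#' are kept 0-based half-open.
#'
#' @param path file path (plain or gzip) or a character vector of lines.
#' @return exon table (see package docs), with strand-aware `ordinal`.
#' @export
read_refflat <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  } else as.character(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_exon_table())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop("malformed RefFlat record at line ", i, ": expected 11 fields, got ",
           length(f))
    strand <- f[4]
    if (!strand %in% c("+", "-"))
      stop("malformed RefFlat record at line ", i, ": unknown strand '",
           strand, "'")
    n_ex <- as.integer(f[9])
    starts <- as.integer(strsplit(f[10], ",", fixed = TRUE)[[1]])
    ends <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    if (length(starts) != n_ex || length(ends) != n_ex)
      stop("malformed RefFlat record at line ", i, ": exonCount ", n_ex,
           " does not match ", length(starts), " starts / ", length(ends),
           " ends")
    if (any(ends <= starts))
      stop("malformed RefFlat record at line ", i, ": empty exon")
    recs[[i]] <- data.table(
      gene = f[1], transcript_id = f[2], chrom = f[3], strand = strand,
      tx_start = as.integer(f[5]), tx_end = as.integer(f[6]),
      exon_idx = seq_len(n_ex), start = starts, end = ends,
      ordinal = if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex)))
  }
  rbindlist(recs)
}

empty_exon_table <- function() {
  data.table(gene = character(), transcript_id = character(),
             chrom = character(), strand = character(),
             tx_start = integer(), tx_end = integer(), exon_idx = integer(),
             start = integer(), end = integer(), ordinal = integer())
}

#' Write gene models to a RefFlat file
#' @param exons exon table as returned by [read_refflat()].
#' @param path output path (".gz" suffix gives gzip).
#' @export
write_refflat <- function(exons, path) {
  exons <- as.data.table(exons)
  recs <- exons[order(match(transcript_id, unique(transcript_id)), start),
    .(line = paste(gene[1], transcript_id[1], chrom[1], strand[1],
                   tx_start[1], tx_end[1], tx_start[1], tx_end[1], .N,
                   paste0(paste(start, collapse = ","), ","),
                   paste0(paste(end, collapse = ","), ","), sep = "\t")),
    by = transcript_id]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(recs$line, con)
  invisible(path)
}

#' Derive introns with strand-aware ordinal positions
#'
#' Intron N lies between exons of ordinal N and N+1 in transcription order
#' (the intron between exons 1 and 2 is intron 1). Single-exon transcripts
#' contribute nothing.
#'
#' @param exons exon table.
#' @return data.table gene, transcript_id, chrom, strand, start, end,
#'   ordinal (one row per intron).
#' @export
derive_introns <- function(exons) {
  exons <- as.data.table(exons)
  if (!nrow(exons))
    return(data.table(gene = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      ordinal = integer()))
  introns <- exons[order(start),
    if (.N > 1L) .(gene = gene[1], chrom = chrom[1], strand = strand[1],
                   start = head(end, -1L), end = tail(start, -1L),
                   genomic_idx = seq_len(.N - 1L)),
    by = transcript_id]
  if (!nrow(introns))
    return(data.table(gene = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      ordinal = integer()))
  introns[, ordinal := if (strand[1] == "+") genomic_idx else
            max(genomic_idx) - genomic_idx + 1L, by = transcript_id]
  introns[, genomic_idx := NULL]
  setcolorder(introns, c("gene", "transcript_id", "chrom", "strand",
                         "start", "end", "ordinal"))
  introns[]
}

#' Per-gene span, length and exon count
#'
#' Gene span runs from the minimum start to the maximum end over the
#' gene's transcripts; exon count is the maximum over isoforms.
#'
#' @param exons exon table.
#' @return data.table gene, chrom, strand, start, end, gene_length,
#'   n_exons, n_isoforms.
#' @export
gene_spans <- function(exons) {
  exons <- as.data.table(exons)
  per_tx <- exons[, .(gene = gene[1], chrom = chrom[1], strand = strand[1],
                      start = min(start), end = max(end), n_ex = .N),
                  by = transcript_id]
  per_tx[, .(chrom = chrom[1], strand = strand[1], start = min(start),
             end = max(end), gene_length = max(end) - min(start),
             n_exons = max(n_ex), n_isoforms = .N),
         by = gene]
}

#' Spliced transcript sequences in transcription orientation
#'
#' @param exons exon table.
#' @param genome named [Biostrings::DNAStringSet] of chromosomes.
#' @return DNAStringSet named by transcript_id.
#' @export
transcript_sequences <- function(exons, genome) {
  exons <- as.data.table(exons)
  tx_ids <- unique(exons$transcript_id)
  seqs <- vapply(tx_ids, function(tx) {
    e <- exons[transcript_id == tx][order(start)]
    s <- paste(vapply(seq_len(nrow(e)), function(i)
      as.character(Biostrings::subseq(genome[[e$chrom[i]]],
                                      e$start[i] + 1L, e$end[i])),
      character(1)), collapse = "")
    if (e$strand[1] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, tx_ids))
}

#' Exon sequences of one transcript in transcription order
#'
#' @param exons exon table rows of a single transcript.
#' @param genome named DNAStringSet.
#' @return character vector of exon sequences, element i = exon of
#'   ordinal i, each in transcription orientation.
#' @keywords internal
exon_sequences_tx <- function(exons, genome) {
  e <- as.data.table(exons)[order(ordinal)]
  vapply(seq_len(nrow(e)), function(i) {
    s <- as.character(Biostrings::subseq(genome[[e$chrom[i]]],
                                         e$start[i] + 1L, e$end[i]))
    if (e$strand[1] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
}

#' Read gene models from GTF exon features
#'
#' Only `exon` features are used; coordinates are converted to the
#' package's 0-based half-open convention on read and strand-aware
#' ordinals are assigned.
#'
#' @param path GTF file (plain or gzip) with `gene_id`/`gene_name` and
#'   `transcript_id` attributes.
#' @return exon table, as from [read_refflat()].
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) return(empty_exon_table())
  gene <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  ex <- data.table(
    gene = gene, transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  if (any(!ex$strand %in% c("+", "-")))
    stop("GTF exon with unknown strand")
  ex <- ex[order(transcript_id, start)]
  ex[, `:=`(tx_start = min(start), tx_end = max(end),
            exon_idx = seq_len(.N),
            ordinal = if (strand[1] == "+") seq_len(.N) else
              rev(seq_len(.N))),
     by = transcript_id]
  setcolorder(ex, c("gene", "transcript_id", "chrom", "strand",
                    "tx_start", "tx_end", "exon_idx", "start", "end",
                    "ordinal"))
  ex[]
}
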