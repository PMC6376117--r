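# Genomic intervals as plain data.tables with columns chrom, start, end
# (0-based half-open) and optionally strand. Conversion to GRanges is
# confined to these helpers so the 0/1-based switch happens in one place.

#' Convert an interval table to GRanges
#'
#' @param x data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `strand`.
#' @param keep_strand use the strand column if present.
#' @return A [GenomicRanges::GRanges] (1-based closed, as GRanges requires).
#' @export
intervals_to_granges <- function(x, keep_strand = TRUE) {
  x <- as.data.table(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start < 0 | x$end <= x$start))
    stop("invalid interval: need 0 <= start < end")
  strand <- if (keep_strand && "strand" %in% names(x) && nrow(x))
    ifelse(x$strand %in% c("+", "-"), x$strand, "*") else "*"
  GenomicRanges::GRanges(
    seqnames = if (nrow(x)) x$chrom else character(),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (nrow(x)) strand else character())
}

#' Convert GRanges to a 0-based half-open interval table
#' @param gr A GRanges object.
#' @return data.table with chrom/start/end/strand.
#' @export
granges_to_intervals <- function(gr) {
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
}

#' Intersect two interval sets with a minimum query-overlap fraction
#'
#' Reports every (query, subject) pair whose overlap covers at least
#' `min_fraction_of_query` of the query interval, the semantics of
#' `intersectBed -f`. Strand is ignored; arithmetic is half-open.
#'
#' @param query,subject interval tables (chrom, start, end).
#' @param min_fraction_of_query required overlap as a fraction of the query
#'   length, in (0, 1].
#' @return data.table with `qidx`, `sidx` (row indices into the inputs) and
#'   `overlap_nt`. Empty inputs give an empty result.
#' @export
intersect_intervals <- function(query, subject, min_fraction_of_query = 1e-9) {
  stopifnot(min_fraction_of_query > 0, min_fraction_of_query <= 1)
  query <- as.data.table(query); subject <- as.data.table(subject)
  empty <- data.table(qidx = integer(), sidx = integer(),
                      overlap_nt = integer())
  if (!nrow(query) || !nrow(subject)) return(empty)
  qgr <- intervals_to_granges(query, keep_strand = FALSE)
  sgr <- intervals_to_granges(subject, keep_strand = FALSE)
  hits <- GenomicRanges::findOverlaps(qgr, sgr, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    qgr[S4Vectors::queryHits(hits)], sgr[S4Vectors::subjectHits(hits)]))
  qlen <- query$end - query$start
  keep <- ov >= min_fraction_of_query * qlen[S4Vectors::queryHits(hits)]
  data.table(qidx = S4Vectors::queryHits(hits)[keep],
             sidx = S4Vectors::subjectHits(hits)[keep],
             overlap_nt = as.integer(ov[keep]))
}

#' Read a BED6 file into an interval table
#' @param path BED file (plain or gzip).
#' @return data.table with chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_intervals(gr)
  out[, `:=`(name = if (!is.null(gr$name)) gr$name else NA_character_,
             score = if (!is.null(gr$score)) gr$score else 0)]
  setcolorder(out, c("chrom", "start", "end", "name", "score", "strand"))
  out[]
}

#' Write an interval table as BED6
#' @param x interval table; optional `name`, `score`, `strand` columns.
#' @param path output path (".gz" suffix gives gzip).
#' @export
write_bed <- function(x, path) {
  x <- as.data.table(x)
  gr <- intervals_to_granges(x)
  gr$name <- if ("name" %in% names(x)) x$name else "."
  gr$score <- if ("score" %in% names(x)) x$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
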