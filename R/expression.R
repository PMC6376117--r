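# Linear-transcript expression: FPKM on the union of exons across a
# gene's isoforms, with an optional exclusion mask (rRNA/tRNA/chrM style).

#' Exonic length per gene (union of exons across isoforms)
#'
#' @param exons exon table.
#' @param mask optional interval table; masked nucleotides are removed
#'   from the union before measuring.
#' @return named integer vector of exonic nt per gene.
#' @export
gene_exonic_length <- function(exons, mask = NULL) {
  exons <- as.data.table(exons)
  out <- integer(0)
  for (g in unique(exons$gene)) {
    gr <- GenomicRanges::reduce(
      intervals_to_granges(exons[gene == g], keep_strand = FALSE))
    if (!is.null(mask) && nrow(as.data.table(mask))) {
      mgr <- GenomicRanges::reduce(
        intervals_to_granges(as.data.table(mask), keep_strand = FALSE))
      gr <- GenomicRanges::setdiff(gr, mgr, ignore.strand = TRUE)
    }
    out[g] <- sum(GenomicRanges::width(gr))
  }
  out
}

#' Compute FPKM from raw counts
#'
#' FPKM = count / (exonic kb x mapped millions), with the gene's exonic
#' length taken as the union of exons across its isoforms.
#'
#' @param counts data.table with columns gene, sample_id, count.
#' @param exons exon table used for exonic lengths.
#' @param mapped_reads named numeric vector of total mapped reads per
#'   sample (all > 0).
#' @param mask optional exclusion interval table (default none).
#' @return data.table gene, sample_id, count, fpkm.
#' @export
compute_fpkm <- function(counts, exons, mapped_reads, mask = NULL) {
  counts <- as.data.table(counts)
  if (any(mapped_reads <= 0)) stop("mapped reads must be > 0 per sample")
  exlen <- gene_exonic_length(exons, mask)
  missing_len <- setdiff(counts$gene, names(exlen))
  if (length(missing_len))
    stop("no exon annotation for gene(s): ",
         paste(missing_len, collapse = ", "))
  if (any(exlen[unique(counts$gene)] == 0))
    stop("zero exonic length for gene(s): ",
         paste(names(which(exlen[unique(counts$gene)] == 0)), collapse = ", "))
  bad <- setdiff(counts$sample_id, names(mapped_reads))
  if (length(bad))
    stop("no mapped-read total for sample(s): ", paste(bad, collapse = ", "))
  out <- copy(counts)
  out[, fpkm := count / (exlen[gene] / 1e3) / (mapped_reads[sample_id] / 1e6)]
  out[]
}

#' Flag expressed genes by mean FPKM over a cell type's samples
#'
#' @param expr output of [compute_fpkm()].
#' @param samples character vector of sample_ids belonging to the cell
#'   type (default all samples in `expr`).
#' @param threshold inclusive mean-FPKM cutoff (default 1).
#' @return character vector of expressed gene symbols.
#' @export
expressed_genes <- function(expr, samples = NULL, threshold = 1) {
  expr <- as.data.table(expr)
  if (!is.null(samples)) expr <- expr[sample_id %in% samples]
  means <- expr[, .(m = mean(fpkm)), by = gene]
  means[m >= threshold, gene]
}
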