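# NET-seq coverage simulation: per-nucleotide expected signal is
# gene_rate x dwell(position), where dwell reflects exon/intron factors,
# boundary stall bumps and optional positional acceleration; each
# replicate adds independent Poisson noise under the master seed.

#' Simulate NET-seq coverage (two replicates)
#'
#' @param sim a `circ_sim`.
#' @param exon_factor,intron_factor,stall_height,stall_width,accel dwell
#'   model parameters (defaults from config).
#' @param circ_exon_factor,circ_intron_factor overrides applied to
#'   circRNA-producing genes only (default: same as other genes).
#' @return list with `rep1`, `rep2` (RleList coverage tracks) and
#'   `expected` (noise-free RleList).
#' @export
simulate_netseq <- function(sim, exon_factor = NULL, intron_factor = NULL,
                            stall_height = NULL, stall_width = NULL,
                            accel = NULL, circ_exon_factor = NULL,
                            circ_intron_factor = NULL) {
  cfg <- sim$config
  ef <- exon_factor %||% cfg$netseq_exon_factor
  inf_ <- intron_factor %||% cfg$netseq_intron_factor
  sh <- stall_height %||% cfg$netseq_stall_height
  sw <- stall_width %||% cfg$netseq_stall_width
  acc <- accel %||% cfg$netseq_accel
  cef <- circ_exon_factor %||% cfg$netseq_circ_exon_factor %||% ef
  cif <- circ_intron_factor %||% cfg$netseq_circ_intron_factor %||% inf_
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 303L)
  chrom <- names(sim$genome)[1]
  clen <- Biostrings::width(sim$genome)[1]
  mu <- numeric(clen)
  circ_genes <- unique(sim$truth$gene)
  for (g in unique(sim$exons$gene)) {
    e <- sim$exons[gene == g][order(start)]
    gs <- e$tx_start[1]; ge <- e$tx_end[1]
    glen <- ge - gs
    is_circ <- g %in% circ_genes
    dwell <- rep(if (is_circ) cif else inf_, glen)
    for (i in seq_len(nrow(e)))
      dwell[(e$start[i] - gs + 1L):(e$end[i] - gs)] <-
        if (is_circ) cef else ef
    if (sh != 1 && sw > 0) {
      for (b in c(e$start, e$end)) {
        lo <- max(b - gs + 1L - sw, 1L); hi <- min(b - gs + sw, glen)
        dwell[lo:hi] <- dwell[lo:hi] * sh
      }
    }
    if (acc != 0) {
      tpos <- if (e$strand[1] == "+") seq_len(glen) else rev(seq_len(glen))
      dwell <- dwell * exp(-acc * (tpos - 1) / glen)
    }
    mu[(gs + 1L):ge] <- cfg$netseq_gene_rate * dwell
  }
  rep1 <- stats::rpois(clen, mu)
  rep2 <- stats::rpois(clen, mu)
  as_track <- function(v)
    IRanges::RleList(setNames(list(S4Vectors::Rle(v)), chrom))
  list(rep1 = as_track(rep1), rep2 = as_track(rep2),
       expected = as_track(mu))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a coverage track as bedGraph
#' @param track RleList coverage track.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  grl <- lapply(names(track), function(ch) {
    r <- track[[ch]]
    rl <- S4Vectors::runLength(r); rv <- S4Vectors::runValue(r)
    ends <- cumsum(rl)
    keep <- rv != 0
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = (ends - rl + 1L)[keep], end = ends[keep]),
      score = as.numeric(rv[keep]))
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file as a coverage track
#' @param path bedGraph path (plain or gzip).
#' @return RleList of per-nucleotide signal.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::coverage(gr, weight = "score")
}
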