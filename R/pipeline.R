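# End-to-end toy run: simulate, detect, score against the planted truth,
# and summarise the positional/span signatures. This is the driver used
# by the worked example, the command-line wrapper and the acceptance
# script.

#' Run the simulate-and-detect pipeline on a toy dataset
#'
#' Generates a synthetic genome with planted circRNAs, simulates the
#' paired-end library, runs the full back-splice detection path
#' (linear-transcriptome subtraction, junction-library matching with
#' anchors and uniqueness, mate-inside-the-circle verification, JPM
#' normalisation, abundance threshold), and scores the detected junction
#' set against the planted truth.
#'
#' @param seed integer master seed.
#' @param config a [sim_config()] (default `sim_config(seed = seed)`).
#' @param det a [detector_config()] (default with the config's read
#'   length).
#' @return list: `sim`, `reads`, `index`, `records` (per-junction counts
#'   and JPM), `detected` (keys passing the abundance filter), `truth`
#'   (keys of the detectable planted circles, i.e. those at least one
#'   read long), `recall`, `precision`, `acceptor_profile`, `span_dist`.
#' @export
run_toy_pipeline <- function(seed = 1L, config = NULL, det = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  if (is.null(det))
    det <- detector_config(read_length = config$read_length)
  sim <- generate_genome_annotation(config)
  reads <- simulate_read_pairs(sim)
  index <- build_backsplice_index(sim$exons, sim$genome, det)
  linear_seqs <- c(transcript_sequences(sim$exons, sim$genome), sim$genome)
  counts <- detect_circ_reads(reads, index, linear_seqs, det)
  counts[, sample_id := "total_rna"]
  mapped <- c(total_rna = reads$mapped_reads)
  records <- count_and_normalize(counts, mapped, index)
  sheet <- data.table(sample_id = "total_rna", cell_type = "toy")
  detected <- filter_by_abundance(records, sheet,
                                  threshold = det$jpm_threshold)
  # a planted circle shorter than one read yields no reads (the read
  # simulator skips it with a warning) and is undetectable by
  # construction; recall is measured over the detectable circles
  truth_keys <- sim$truth[circle_len >= config$read_length, key]
  tp <- length(intersect(detected, truth_keys))
  recall <- if (length(truth_keys)) tp / length(truth_keys) else NA_real_
  precision <- if (length(detected)) tp / length(detected) else NA_real_
  det_iso <- index$by_isoform[key %in% detected]
  ef <- exon_position_frequency(
    sim$exons[gene %in% unique(det_iso$gene)])
  prof <- if (nrow(det_iso))
    backsplice_position_profile(det_iso$acceptor_ordinal, ef) else NULL
  spans <- if (nrow(det_iso))
    circ_exon_span_distribution(unique(det_iso, by = "key")) else NULL
  list(sim = sim, reads = reads, index = index, records = records,
       detected = detected, truth = truth_keys, recall = recall,
       precision = precision, acceptor_profile = prof, span_dist = spans)
}

#' Brute-force junction-read oracle
#'
#' Independent of the detector: counts, for each planted circRNA, the
#' read pairs whose reads contain a junction-crossing substring, by
#' direct string search of every read (and its reverse complement) in
#' the set of junction-spanning windows of the circular sequence.
#'
#' @param reads list with `read1`, `read2`.
#' @param sim a `circ_sim`.
#' @param min_anchor anchor length the windows must respect.
#' @return data.table key, n_pairs (pairs with >= 1 junction-crossing
#'   read whose mate is a substring of the doubled circle).
#' @export
oracle_junction_counts <- function(reads, sim, min_anchor = 8L) {
  out <- list()
  r1 <- as.character(reads$read1); r2 <- as.character(reads$read2)
  rc1 <- as.character(Biostrings::reverseComplement(reads$read1))
  rc2 <- as.character(Biostrings::reverseComplement(reads$read2))
  rl <- nchar(r1[1])
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i]
    cs <- circle_sequence(sim, tr)
    L <- nchar(cs)
    if (L < rl) next
    doubled <- paste0(cs, cs, cs)
    # junction-crossing windows: read-length substrings that span the
    # wrap point with >= min_anchor nt on each side
    starts <- seq(max(L - rl + min_anchor + 1L, 1L), L - min_anchor + 1L)
    wins <- unique(substring(doubled, starts, starts + rl - 1L))
    j1 <- (r1 %in% wins) | (rc1 %in% wins)
    j2 <- (r2 %in% wins) | (rc2 %in% wins)
    mate_in <- function(mf, mr, idx) {
      res <- logical(length(mf))
      res[idx] <- vapply(idx, function(k)
        grepl(mf[k], doubled, fixed = TRUE) ||
          grepl(mr[k], doubled, fixed = TRUE), logical(1))
      res
    }
    ok1 <- mate_in(r2, rc2, which(j1))
    ok2 <- mate_in(r1, rc1, which(j2))
    out[[tr$key]] <- dtab(key = tr$key, n_pairs = sum(ok1 | ok2))
  }
  if (!length(out)) return(dtab(key = character(),
                                      n_pairs = integer()))
  rbindlist(out)
}
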