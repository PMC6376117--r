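# Back-splice junction detection: an annotation-anchored junction
# sequence library is searched with exact (optionally mismatch-tolerant)
# string matching; a pair counts towards a circRNA only when one read maps
# uniquely across a back-splice junction with sufficient anchors and its
# mate lies inside the anticipated circle.

#' Detector configuration
#'
#' @param k flank length (nt) taken from each exon to build junction
#'   sequences; default `read_length - min_anchor` so any read that could
#'   span the junction with valid anchors fits inside the library entry.
#' @param min_anchor minimum matched nt required on each side of the
#'   junction point (default 8).
#' @param max_mismatches maximum substitutions tolerated per read
#'   (default 1).
#' @param jpm_threshold inclusive mean-JPM abundance cutoff (default 0.1).
#' @param read_length read length used to derive `k` when `k` is NULL.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(k = NULL, min_anchor = 8L, max_mismatches = 1L,
                            jpm_threshold = 0.1, read_length = 75L) {
  if (is.null(k)) k <- read_length - min_anchor
  stopifnot(min_anchor > 0, min_anchor <= k, max_mismatches >= 0)
  structure(list(k = as.integer(k), min_anchor = as.integer(min_anchor),
                 max_mismatches = as.integer(max_mismatches),
                 jpm_threshold = jpm_threshold),
            class = "detector_config")
}

#' Build the back-splice junction candidate library
#'
#' One candidate junction per exon pair (acceptor ordinal a <= donor
#' ordinal d) within each transcript, all ordinal positions included
#' (first/last exons are candidates too; erroneous ordinal-1 assignments
#' are reported, not forbidden). The junction sequence is the donor exon's
#' 3' k-mer followed by the acceptor exon's 5' k-mer in transcript
#' orientation, flanks truncated to the exon length where the exon is
#' shorter than k. Candidates are deduplicated across isoforms by
#' junction key (chrom, circle start, circle end, strand) with
#' transcript ids merged.
#'
#' @param exons exon table.
#' @param genome named DNAStringSet.
#' @param config a [detector_config()].
#' @return object of class `bsj_index`: list with `junctions` (data.table,
#'   one row per junction key) and `by_isoform` (one row per (key,
#'   transcript) with that isoform's ordinals).
#' @export
build_backsplice_index <- function(exons, genome,
                                   config = detector_config()) {
  exons <- as.data.table(exons)
  k <- config$k
  iso_rows <- list(); junc_rows <- list()
  for (tx in unique(exons$transcript_id)) {
    e <- exons[transcript_id == tx][order(ordinal)]
    seqs <- exon_sequences_tx(e, genome)
    n_ex <- nrow(e)
    lens <- nchar(seqs)
    offs <- cumsum(c(0L, head(lens, -1L)))
    for (a in seq_len(n_ex)) for (d in a:n_ex) {
      span_ex <- e[a:d]
      cs <- min(span_ex$start); ce <- max(span_ex$end)
      key <- paste(e$chrom[1], cs, ce, e$strand[1], sep = ":")
      don_flank <- substr(seqs[d], max(lens[d] - k + 1L, 1L), lens[d])
      acc_flank <- substr(seqs[a], 1L, min(k, lens[a]))
      circ_seq <- paste(seqs[a:d], collapse = "")
      iso_rows[[length(iso_rows) + 1L]] <- dtab(
        key = key, transcript_id = tx, gene = e$gene[1],
        acceptor_ordinal = a, donor_ordinal = d)
      junc_rows[[key]] <- dtab(
        key = key, gene = e$gene[1], chrom = e$chrom[1],
        strand = e$strand[1], circ_start = cs, circ_end = ce,
        acceptor_ordinal = a, donor_ordinal = d,
        junc_seq = paste0(don_flank, acc_flank),
        junc_point = nchar(don_flank), circ_seq = circ_seq)
    }
  }
  by_isoform <- if (length(iso_rows)) rbindlist(iso_rows) else
    dtab(key = character(), transcript_id = character(),
               gene = character(), acceptor_ordinal = integer(),
               donor_ordinal = integer())
  junctions <- if (length(junc_rows)) rbindlist(junc_rows) else
    data.table()
  if (nrow(junctions)) {
    tx_by_key <- by_isoform[, .(transcript_ids = paste(unique(transcript_id),
                                                       collapse = ",")),
                            by = key]
    junctions <- merge(junctions, tx_by_key, by = "key", sort = FALSE)
  }
  structure(list(junctions = junctions, by_isoform = by_isoform,
                 config = config), class = "bsj_index")
}

#' @export
print.bsj_index <- function(x, ...) {
  cat("bsj_index:", nrow(x$junctions), "candidate junctions over",
      length(unique(x$junctions$gene)), "genes (k =", x$config$k, ")\n")
  invisible(x)
}

# exact membership of each read (either orientation) in a subject set
.match_any_exact <- function(reads, subjects) {
  if (!length(reads)) return(logical(0))
  hit <- rep(FALSE, length(reads))
  for (or in 1:2) {
    qry <- if (or == 1) reads else Biostrings::reverseComplement(reads)
    names(qry) <- NULL
    pd <- Biostrings::PDict(qry)
    m <- Biostrings::vwhichPDict(pd, subjects)
    hit <- hit | seq_along(reads) %in% unique(unlist(m))
  }
  hit
}

# concatenate a sequence set with N separators; returns the lookup
# needed to map concat positions back to entries
.concat_subjects <- function(seqs) {
  chr <- as.character(seqs)
  lens <- nchar(chr)
  offs <- cumsum(c(0, head(lens + 1, -1)))   # entry start - 1 in concat
  list(chr = paste(chr, collapse = "N"),
       dna = Biostrings::DNAString(paste(chr, collapse = "N")),
       offs = offs, lens = lens)
}

.count_mismatches <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

# seed-and-extend mismatch-tolerant search of reads (one orientation) in
# a concatenated subject set: a read within max_mm substitutions of a
# subject window must share one of max_mm+1 exact segments with it
# (pigeonhole), so exact segment hits are extended and verified.
# Returns data.table(read_idx, subj_idx, offset, mismatches).
.mm_hits_oriented <- function(reads, cc, max_mm) {
  empty <- data.table(read_idx = integer(), subj_idx = integer(),
                      offset = integer(), mismatches = integer())
  if (!length(reads)) return(empty)
  reads_chr <- as.character(reads)
  out <- list()
  for (w in unique(nchar(reads_chr))) {
    grp <- which(nchar(reads_chr) == w)
    seg_len <- w %/% (max_mm + 1L)
    if (seg_len < 1L) next
    cand <- list()
    for (j in 0:max_mm) {
      sq <- j * seg_len + 1L
      segs <- Biostrings::DNAStringSet(unname(substring(reads_chr[grp], sq,
                                                        sq + seg_len - 1L)))
      mi <- Biostrings::matchPDict(Biostrings::PDict(segs), cc$dna)
      st <- BiocGenerics::start(mi)
      n_per <- S4Vectors::elementNROWS(st)
      if (!sum(n_per)) next
      starts <- unlist(st, use.names = FALSE)
      cand[[length(cand) + 1L]] <- data.table(
        read_idx = rep(grp, n_per), implied = starts - (sq - 1L))
    }
    if (!length(cand)) next
    cand <- unique(rbindlist(cand))
    si <- findInterval(cand$implied, cc$offs + 1)
    in_entry <- si >= 1 & cand$implied >= cc$offs[si] + 1 &
      (cand$implied + w - 1L) <= cc$offs[si] + cc$lens[si]
    cand <- cand[in_entry]; si <- si[in_entry]
    if (!nrow(cand)) next
    win <- substring(cc$chr, cand$implied, cand$implied + w - 1L)
    mm <- .count_mismatches(win, reads_chr[cand$read_idx])
    keep <- mm <= max_mm
    out[[length(out) + 1L]] <- data.table(
      read_idx = cand$read_idx[keep], subj_idx = si[keep],
      offset = as.integer(cand$implied[keep] - cc$offs[si[keep]]),
      mismatches = as.integer(mm[keep]))
  }
  if (!length(out)) return(empty)
  unique(rbindlist(out))
}

# mismatch-tolerant membership of reads in a subject set (both
# orientations); returns a logical per read
.match_any_mm <- function(reads, subjects, max_mm) {
  if (!length(reads)) return(logical(0))
  cc <- .concat_subjects(subjects)
  hit <- rep(FALSE, length(reads))
  for (or in 1:2) {
    qry <- if (or == 1) reads else Biostrings::reverseComplement(reads)
    h <- .mm_hits_oriented(qry, cc, max_mm)
    hit[unique(h$read_idx)] <- TRUE
  }
  hit
}

#' Classify read pairs against the linear transcriptome
#'
#' A pair is `linear` iff both reads match a linear reference sequence
#' (spliced transcript or genome) contiguously within the mismatch
#' budget, in either orientation; only `candidate` pairs proceed to
#' junction detection.
#'
#' @param reads list with `read1`, `read2` DNAStringSets.
#' @param linear_seqs DNAStringSet of spliced transcripts (the genome may
#'   be appended to also absorb unspliced/intronic pairs).
#' @param config a [detector_config()].
#' @return character vector per pair: "linear" or "candidate".
#' @export
classify_linear <- function(reads, linear_seqs,
                            config = detector_config()) {
  l1 <- .match_any_exact(reads$read1, linear_seqs)
  l2 <- .match_any_exact(reads$read2, linear_seqs)
  if (config$max_mismatches > 0L) {
    if (any(!l1))
      l1[!l1] <- .match_any_mm(reads$read1[!l1], linear_seqs,
                               config$max_mismatches)
    if (any(!l2))
      l2[!l2] <- .match_any_mm(reads$read2[!l2], linear_seqs,
                               config$max_mismatches)
  }
  ifelse(l1 & l2, "linear", "candidate")
}

# all exact occurrences of reads within junction sequences:
# data.table(read_idx, junc_idx, offset (1-based in junc_seq), mismatches).
# The library is concatenated with N separators so one matchPDict pass
# covers it; reads contain no N, so matches never straddle entries.
.junction_hits_exact <- function(reads, junc_seqs) {
  lens <- nchar(junc_seqs)
  offs <- cumsum(c(0L, head(lens + 1L, -1L)))   # entry start - 1 in concat
  concat <- Biostrings::DNAString(paste(junc_seqs, collapse = "N"))
  out <- list()
  for (or in 1:2) {
    qry <- if (or == 1) reads else Biostrings::reverseComplement(reads)
    names(qry) <- NULL
    pd <- Biostrings::PDict(qry)
    mi <- Biostrings::matchPDict(pd, concat)
    st <- BiocGenerics::start(mi)
    n_per <- S4Vectors::elementNROWS(st)
    if (!sum(n_per)) next
    starts <- unlist(st, use.names = FALSE)
    ji <- findInterval(starts, offs + 1L)
    out[[or]] <- data.table(read_idx = rep(seq_along(qry), n_per),
                            junc_idx = ji,
                            offset = starts - offs[ji],
                            mismatches = 0L)
  }
  if (!length(out)) return(data.table(read_idx = integer(),
                                      junc_idx = integer(),
                                      offset = integer(),
                                      mismatches = integer()))
  unique(rbindlist(out))
}

#' Detect junction-spanning reads
#'
#' A hit requires the read to match a junction library sequence with at
#' least `min_anchor` matched nt on both sides of the junction point and
#' at most `max_mismatches` substitutions. Reads whose best matches hit
#' more than one junction key are discarded (uniqueness rule).
#'
#' @param reads DNAStringSet of candidate reads.
#' @param index a `bsj_index`.
#' @param config a [detector_config()].
#' @return data.table read_idx, key, offset, mismatches (unique best hit
#'   per read).
#' @export
detect_junction_reads <- function(reads, index,
                                  config = detector_config()) {
  jt <- index$junctions
  empty <- dtab(read_idx = integer(), key = character(),
                      offset = integer(), mismatches = integer())
  if (!length(reads) || !nrow(jt)) return(empty)
  hits <- .junction_hits_exact(reads, jt$junc_seq)
  rl <- Biostrings::width(reads)
  if (config$max_mismatches > 0L) {
    unmatched <- setdiff(seq_along(reads), unique(hits$read_idx))
    if (length(unmatched)) {
      cc <- .concat_subjects(jt$junc_seq)
      mm_rows <- list()
      for (or in 1:2) {
        qry <- if (or == 1) reads[unmatched] else
          Biostrings::reverseComplement(reads[unmatched])
        h <- .mm_hits_oriented(qry, cc, config$max_mismatches)
        if (nrow(h))
          mm_rows[[or]] <- data.table(read_idx = unmatched[h$read_idx],
                                      junc_idx = h$subj_idx,
                                      offset = h$offset,
                                      mismatches = h$mismatches)
      }
      if (length(mm_rows))
        hits <- unique(rbind(hits, rbindlist(mm_rows)))
    }
  }
  if (!nrow(hits)) return(empty)
  # anchor rule: the read must extend min_anchor nt past the junction
  # point on both sides
  jp <- jt$junc_point[hits$junc_idx]
  left <- jp - hits$offset + 1L
  right <- hits$offset + rl[hits$read_idx] - 1L - jp
  hits <- hits[left >= config$min_anchor & right >= config$min_anchor]
  if (!nrow(hits)) return(empty)
  hits[, key := jt$key[junc_idx]]
  # uniqueness: best (fewest-mismatch) hits must name a single junction key
  best <- hits[, .SD[mismatches == min(mismatches)], by = read_idx]
  uniq <- best[, .(nkeys = uniqueN(key)), by = read_idx][nkeys == 1L,
                                                         read_idx]
  best[read_idx %in% uniq,
       .(offset = offset[1], mismatches = mismatches[1]),
       by = .(read_idx, key)]
}

#' Verify that the mate lies inside the anticipated circle
#'
#' The mate (either orientation) must match the circular spliced sequence
#' of the candidate circRNA: equivalently it lies within the circle's
#' exons or itself crosses the back-splice junction. Matching is against
#' the doubled circular sequence so wrap-spanning mates are found.
#'
#' @param hits output of [detect_junction_reads()].
#' @param mates DNAStringSet of mate reads, parallel to the read set the
#'   hits were computed on.
#' @param index a `bsj_index`.
#' @param config a [detector_config()].
#' @return `hits` restricted to verified rows.
#' @export
verify_mate_inside <- function(hits, mates, index,
                               config = detector_config()) {
  if (!nrow(hits)) return(hits)
  jt <- index$junctions
  circ_of <- setNames(jt$circ_seq, jt$key)
  mate_f <- as.character(mates)
  mate_r <- as.character(Biostrings::reverseComplement(mates))
  doubled_cache <- new.env(parent = emptyenv())
  rl <- Biostrings::width(mates)
  ok <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ky <- hits$key[i]
    doubled <- get0(ky, envir = doubled_cache)
    if (is.null(doubled)) {
      cs <- circ_of[[ky]]
      reps <- max(2L, ceiling(max(rl) / nchar(cs)) + 1L)
      doubled <- paste(rep(cs, reps), collapse = "")
      assign(ky, doubled, envir = doubled_cache)
    }
    ri <- hits$read_idx[i]
    found <- grepl(mate_f[ri], doubled, fixed = TRUE) ||
      grepl(mate_r[ri], doubled, fixed = TRUE)
    if (!found && config$max_mismatches > 0L) {
      dd <- Biostrings::DNAString(doubled)
      found <- length(Biostrings::matchPattern(
        mates[[ri]], dd, max.mismatch = config$max_mismatches)) > 0 ||
        length(Biostrings::matchPattern(
          Biostrings::reverseComplement(mates[[ri]]), dd,
          max.mismatch = config$max_mismatches)) > 0
    }
    ok[i] <- found
  }
  hits[ok]
}

#' Full per-sample detection: classify, detect, verify, count
#'
#' @param reads list with `read1`, `read2` (named DNAStringSets).
#' @param index a `bsj_index`.
#' @param linear_seqs DNAStringSet of linear reference sequences.
#' @param config a [detector_config()].
#' @return data.table key, n_pairs (verified junction pairs per junction
#'   key; a pair whose both reads hit the same junction counts once).
#' @export
detect_circ_reads <- function(reads, index, linear_seqs,
                              config = detector_config()) {
  lab <- classify_linear(reads, linear_seqs, config)
  cand <- which(lab == "candidate")
  pair_hits <- list()
  for (m in 1:2) {
    rs <- reads[[paste0("read", m)]][cand]
    hits <- detect_junction_reads(rs, index, config)
    hits <- verify_mate_inside(hits, reads[[paste0("read", 3 - m)]][cand],
                               index, config)
    if (nrow(hits))
      pair_hits[[m]] <- dtab(pair_idx = cand[hits$read_idx],
                                   key = hits$key)
  }
  if (!length(pair_hits))
    return(dtab(key = character(), n_pairs = integer()))
  all_hits <- unique(rbindlist(pair_hits))    # pair counted once per key
  all_hits[, .(n_pairs = .N), by = key]
}

#' Count junction pairs and normalise to JPM
#'
#' JPM(sample) = verified junction pairs / (mapped reads / 1e6). Records
#' with zero counts in all samples are omitted.
#'
#' @param counts data.table sample_id, key, n_pairs.
#' @param mapped_reads named numeric vector of per-sample mapped totals
#'   (all > 0).
#' @param index optional `bsj_index` to annotate gene/ordinals/span.
#' @return data.table sample_id, key, n_pairs, jpm (+ annotation columns
#'   when `index` given).
#' @export
count_and_normalize <- function(counts, mapped_reads, index = NULL) {
  counts <- as.data.table(counts)
  if (any(mapped_reads <= 0)) stop("sample with zero mapped reads")
  bad <- setdiff(counts$sample_id, names(mapped_reads))
  if (length(bad)) stop("no mapped total for sample(s): ",
                        paste(bad, collapse = ", "))
  out <- counts[n_pairs > 0]
  out[, jpm := n_pairs / (mapped_reads[sample_id] / 1e6)]
  if (!is.null(index))
    out <- merge(out, index$junctions[, .(key, gene, acceptor_ordinal,
                                          donor_ordinal)],
                 by = "key", all.x = TRUE, sort = FALSE)
  out[]
}

#' Abundance filter with polysome-fraction rescue
#'
#' A circRNA is kept iff its mean JPM across the cell type's samples is
#' at or above the threshold, or (when fraction data are supplied) its
#' mean JPM across the eight ribosomal fractions is at or above the
#' threshold. Both comparisons are inclusive.
#'
#' @param records data.table sample_id, key, jpm (long form; absent
#'   (key, sample) combinations count as 0).
#' @param sample_sheet data.table sample_id, cell_type.
#' @param threshold inclusive JPM cutoff (default 0.1).
#' @param fraction_matrix optional output of [build_fraction_matrix()]
#'   enabling the rescue rule.
#' @return character vector of retained junction keys.
#' @export
filter_by_abundance <- function(records, sample_sheet, threshold = 0.1,
                                fraction_matrix = NULL) {
  records <- as.data.table(records)
  sheet <- as.data.table(sample_sheet)
  keys <- unique(records$key)
  if (!length(keys)) return(character(0))
  grid <- CJ(key = keys, sample_id = sheet$sample_id)
  grid <- merge(grid, records[, .(key, sample_id, jpm)],
                by = c("key", "sample_id"), all.x = TRUE)
  grid[is.na(jpm), jpm := 0]
  grid <- merge(grid, sheet, by = "sample_id")
  means <- grid[, .(mean_jpm = mean(jpm)), by = .(key, cell_type)]
  kept <- unique(means[mean_jpm >= threshold, key])
  if (!is.null(fraction_matrix)) {
    fm <- as.data.table(fraction_matrix)
    fcols <- paste0("f", 1:8)
    rescue <- fm[rowMeans(as.matrix(fm[, ..fcols])) >= threshold, key]
    kept <- union(kept, intersect(keys, rescue))
  }
  sort(kept)
}

#' Overlap between two identifier sets
#'
#' @param set_a,set_b character vectors (gene symbols or junction keys).
#' @param denominator_set the set whose size forms the denominator.
#' @return list `n_overlap`, `n_denominator`, `percent` (rounded to the
#'   nearest integer).
#' @export
overlap_summary <- function(set_a, set_b, denominator_set) {
  if (!length(denominator_set)) stop("empty denominator set")
  n_ov <- length(intersect(set_a, set_b))
  list(n_overlap = n_ov, n_denominator = length(denominator_set),
       percent = round(100 * n_ov / length(denominator_set)))
}
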