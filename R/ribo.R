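# Polysome-fraction analysis: per-fraction JPM matrices, the calculated
# free (ribosome non-associated) pool, translation-candidate selection,
# circular ORF scanning and feature enrichment.

FRACTION_COLS <- paste0("f", 1:8)

#' Build the circRNA fraction matrix
#'
#' One row per junction key, columns `total` and `f1`..`f8`, values JPM
#' computed with each library's own mapped total. Columns are matched by
#' label, so input order is immaterial. The derived `free_star` column is
#' 9 x total - sum(fractions), floored at 0 for reporting with the raw
#' value kept in `free_star_raw`.
#'
#' @param counts data.table sample_id, key, n_pairs where sample_id takes
#'   the values "total", "f1".."f8".
#' @param mapped_reads named numeric vector over the same nine labels.
#' @return data.table key, total, f1..f8, free_star_raw, free_star.
#' @export
build_fraction_matrix <- function(counts, mapped_reads) {
  need <- c("total", FRACTION_COLS)
  missing_col <- setdiff(need, names(mapped_reads))
  if (length(missing_col))
    stop("missing fraction column(s): ", paste(missing_col, collapse = ", "))
  counts <- as.data.table(counts)[sample_id %in% need]
  jm <- count_and_normalize(counts, mapped_reads)
  wide <- dcast(jm, key ~ sample_id, value.var = "jpm", fill = 0)
  for (cn in setdiff(need, names(wide))) wide[, (cn) := 0]
  setcolorder(wide, c("key", need))
  wide[, free_star_raw := 9 * total -
         rowSums(as.matrix(.SD)), .SDcols = FRACTION_COLS]
  wide[, free_star := pmax(free_star_raw, 0)]
  wide[]
}

#' Ribosome non-associated (Free*) value
#'
#' Free* = 9 x total cytoplasmic - (monosomes + ... + octa(+)somes), in
#' JPM, exactly as defined for the sedimentation analysis. Negative
#' results are flagged and floored at 0 for reporting.
#'
#' @param total total-cytoplasmic JPM (scalar).
#' @param fractions numeric vector of exactly eight fraction JPM values.
#' @return list `raw`, `value` (floored at 0), `flagged` (TRUE when raw
#'   was negative).
#' @export
compute_free <- function(total, fractions) {
  if (length(fractions) != 8L)
    stop("need exactly 8 fraction values, got ", length(fractions))
  raw <- 9 * total - sum(fractions)
  list(raw = raw, value = max(raw, 0), flagged = raw < 0)
}

#' Select translation-candidate (tc) circRNAs
#'
#' A circRNA is a translation candidate iff the mean of its eight
#' ribosomal-fraction JPM values is at or above the threshold (inclusive);
#' the total column is not used.
#'
#' @param fraction_matrix output of [build_fraction_matrix()].
#' @param threshold inclusive mean-JPM cutoff (default 0.1).
#' @return character vector of tc junction keys.
#' @export
select_tc_circrnas <- function(fraction_matrix, threshold = 0.1) {
  fm <- as.data.table(fraction_matrix)
  fm[rowMeans(as.matrix(fm[, .SD, .SDcols = FRACTION_COLS])) >= threshold,
     key]
}

START_CODONS <- c("ATG", "CTG", "GTG")
STOP_CODONS <- c("TAG", "TAA", "TGA")

#' Scan a circular sequence for open reading frames
#'
#' Every AUG/CUG/GUG start position is walked codon-by-codon around the
#' circle for up to three full passes of the sequence; the first in-frame
#' UAG/UAA/UGA terminates the ORF. If no stop appears within three passes
#' the ORF is flagged as an infinite loop (possible when the circle
#' length is a multiple of 3). The back-splice junction is implicit
#' between the last and first nucleotide; `crosses_junction` marks ORFs
#' whose codon walk passes that point.
#'
#' @param seq character scalar or DNA/RNAString: the circle's spliced
#'   exonic sequence (>= 3 nt).
#' @param start_codons start codon set (default AUG + near-cognate CUG,
#'   GUG; DNA alphabet).
#' @return data.table: start (1-based position on the circle), codon,
#'   context (3 nt either side of the start codon, circular), frame
#'   (start - 1 mod 3), stop_pos (1-based position of the stop codon, NA
#'   for infinite loops), n_codons (codons from start up to and including
#'   the stop; NA for infinite loops), infinite_loop, crosses_junction.
#' @export
find_circ_orfs <- function(seq, start_codons = START_CODONS) {
  s <- toupper(gsub("U", "T", as.character(seq)))
  L <- nchar(s)
  if (L < 3L) stop("sequence shorter than 3 nt")
  ch <- strsplit(s, "")[[1]]
  codon_at <- function(p0) {    # p0 0-based start on circle
    paste(ch[(p0 + 0:2) %% L + 1L], collapse = "")
  }
  rows <- list()
  for (p0 in 0:(L - 1L)) {
    cod <- codon_at(p0)
    if (!cod %in% start_codons) next
    # at most three passes of the circle = L codons (3L nt)
    stop_i <- NA_integer_
    for (step in seq_len(L)[-1]) {
      cc <- codon_at((p0 + 3L * (step - 1L)) %% L)
      if (cc %in% STOP_CODONS) { stop_i <- step; break }
    }
    infinite <- is.na(stop_i)
    walked_nt <- if (infinite) 3L * L else 3L * stop_i
    ctx <- paste(ch[((p0 - 3L):(p0 + 5L)) %% L + 1L], collapse = "")
    rows[[length(rows) + 1L]] <- data.table(
      start = p0 + 1L, codon = cod, context = ctx, frame = p0 %% 3L,
      stop_pos = if (infinite) NA_integer_ else
        (p0 + 3L * (stop_i - 1L)) %% L + 1L,
      n_codons = if (infinite) NA_integer_ else stop_i,
      infinite_loop = infinite,
      crosses_junction = (p0 + walked_nt) > L)
  }
  if (!length(rows))
    return(data.table(start = integer(), codon = character(),
                      context = character(), frame = integer(),
                      stop_pos = integer(), n_codons = integer(),
                      infinite_loop = logical(),
                      crosses_junction = logical()))
  rbindlist(rows)
}

#' Count m6A sites inside circRNA exons
#'
#' Sites (single-nucleotide intervals) are pooled and deduplicated, then
#' counted per circRNA with any-overlap semantics against the circle's
#' exon intervals.
#'
#' @param circ_exons interval table with a `key` column identifying the
#'   circRNA each exon belongs to.
#' @param m6a_sites interval table of single-nt sites (duplicates allowed;
#'   deduplicated before counting).
#' @return data.table key, n_sites (keys with no site reported as 0).
#' @export
m6a_overlap <- function(circ_exons, m6a_sites) {
  circ_exons <- as.data.table(circ_exons)
  sites <- unique(as.data.table(m6a_sites)[, .(chrom, start, end)])
  out <- dtab(key = unique(circ_exons$key), n_sites = 0L)
  if (!nrow(sites) || !nrow(circ_exons)) return(out)
  ov <- intersect_intervals(sites, circ_exons, min_fraction_of_query = 1e-9)
  if (!nrow(ov)) return(out)
  hit <- unique(dtab(site = ov$qidx,
                           key = circ_exons$key[ov$sidx]))
  cnt <- hit[, .(n_sites = .N), by = key]
  out <- merge(out[, .(key)], cnt, by = "key", all.x = TRUE)
  out[is.na(n_sites), n_sites := 0L]
  out[]
}

#' Binary-feature enrichment between circRNA sets
#'
#' Two-sample proportion test (continuity-corrected chi-squared) of a
#' binary feature between, e.g., translation-candidate and non-ribosomal
#' circRNAs.
#'
#' @param feature_a,feature_b logical vectors: the feature per member of
#'   each set (both non-empty).
#' @return list as [proportion_test()].
#' @export
feature_enrichment <- function(feature_a, feature_b) {
  if (!length(feature_a) || !length(feature_b))
    stop("both sets must be non-empty")
  proportion_test(sum(feature_a), length(feature_a),
                  sum(feature_b), length(feature_b))
}
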