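# Pol II dwell analysis from nascent-RNA coverage. Pipeline order is
# fixed: combine replicates (positionwise mean, missing positions = 0),
# cap per-nucleotide counts, then measure per-region densities and
# exon-scaled metagene profiles.

#' Average coverage tracks positionwise
#'
#' @param tracks list of RleList coverage tracks (>= 1). Chromosomes must
#'   agree by name; a position present in only some tracks contributes 0
#'   for the others.
#' @return RleList: positionwise arithmetic mean.
#' @export
combine_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  if (length(tracks) == 1L) return(tracks[[1]])
  chroms <- unique(unlist(lapply(tracks, names)))
  only_some <- !all(vapply(tracks, function(t)
    setequal(names(t), chroms), logical(1)))
  if (only_some)
    stop("chromosome name mismatch between replicate tracks")
  out <- lapply(chroms, function(ch) {
    rles <- lapply(tracks, `[[`, ch)
    maxlen <- max(vapply(rles, length, integer(1)))
    acc <- S4Vectors::Rle(0, maxlen)
    for (r in rles) {
      if (length(r) < maxlen)
        r <- c(r, S4Vectors::Rle(0, maxlen - length(r)))
      acc <- acc + r
    }
    acc / length(tracks)
  })
  IRanges::RleList(setNames(out, chroms))
}

#' Cap per-nucleotide signal
#'
#' Limits the maximum count at any single position to `cap`, guarding
#' region averages against rare extreme loci. Idempotent.
#'
#' @param track RleList coverage track.
#' @param cap maximum value (default 10).
#' @return capped RleList.
#' @export
cap_track <- function(track, cap = 10) {
  stopifnot(cap > 0)
  S4Vectors::endoapply(track, function(r) {
    S4Vectors::runValue(r) <- pmin(S4Vectors::runValue(r), cap)
    r
  })
}

# per-nt signal over [start, end) (0-based half-open); positions beyond
# the track are 0, positions before 1 are NA (off-chromosome)
.track_window <- function(track, chrom, start, end) {
  n <- end - start
  out <- rep(NA_real_, n)
  if (!chrom %in% names(track)) return(out)
  r <- track[[chrom]]
  lo <- max(start + 1L, 1L); hi <- min(end, length(r))
  if (lo <= hi)
    out[(lo - start):(hi - start)] <-
      as.numeric(S4Vectors::window(r, lo, hi))
  if (end > length(r)) {
    over <- (max(length(r), start) + 1L):end
    out[over - start] <- 0
  }
  out
}

#' Signal density over a region
#'
#' Density = sum of per-nucleotide signal over [start, end) divided by
#' the region length ("Pol II/nt" for NET-seq input).
#'
#' @param track RleList (combined and capped).
#' @param regions interval table (chrom, start, end).
#' @return numeric vector of densities, one per region row.
#' @export
region_density <- function(track, regions) {
  regions <- as.data.table(regions)
  if (nrow(regions) && any(regions$end <= regions$start))
    stop("zero-length region")
  vapply(seq_len(nrow(regions)), function(i) {
    v <- .track_window(track, regions$chrom[i], regions$start[i],
                       regions$end[i])
    sum(v, na.rm = TRUE) / (regions$end[i] - regions$start[i])
  }, numeric(1))
}

#' Position-adjusted density comparison
#'
#' Per cell (molecule class x feature role x kind): mean and median
#' density and a two-sided Mann-Whitney P of the circRNA features against
#' their position-adjusted reference features.
#'
#' @param track combined, capped RleList.
#' @param circ_feats interval table with class_, role, kind columns
#'   (e.g. [circ_features()] joined back to genomic intervals).
#' @param ref_feats reference features with the same grouping columns.
#' @return data.table class_, kind, role, n_circ, mean_circ, median_circ,
#'   n_ref, mean_ref, median_ref, p, direction.
#' @export
compare_position_adjusted <- function(track, circ_feats, ref_feats) {
  circ_feats <- as.data.table(circ_feats)
  ref_feats <- as.data.table(ref_feats)
  circ_feats[, density := region_density(track, .SD)]
  ref_feats[, density := region_density(track, .SD)]
  cells <- unique(circ_feats[, .(class_, kind, role)])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i]
    x <- circ_feats[class_ == cc$class_ & kind == cc$kind &
                      role == cc$role, density]
    y <- ref_feats[class_ == cc$class_ & kind == cc$kind &
                     role == cc$role, density]
    if (!length(y))
      stop("empty reference cell: ", cc$class_, "/", cc$kind, "/", cc$role)
    mw <- mann_whitney_u(x, y)
    out[[i]] <- data.table(
      class_ = cc$class_, kind = cc$kind, role = cc$role,
      n_circ = length(x), mean_circ = mean(x),
      median_circ = as.numeric(stats::median(x)),
      n_ref = length(y), mean_ref = mean(y),
      median_ref = as.numeric(stats::median(y)), p = mw$p,
      direction = switch(mw$direction, x = "circ", y = "reference",
                         "equal"))
  }
  rbindlist(out)
}

# rebin a per-nt vector to n_bins by length-weighted linear assignment:
# fractional nucleotides are split proportionally between adjacent bins,
# so a constant input stays exactly constant
.rebin <- function(x, n_bins) {
  L <- length(x)
  if (L == n_bins) return(as.numeric(x))
  cs <- c(0, cumsum(x))
  edges <- seq(0, L, length.out = n_bins + 1L)
  interp <- function(p) {
    i <- floor(p)
    frac <- p - i
    v <- cs[pmin(i, L) + 1L]
    v + ifelse(i < L, frac * x[pmin(i + 1L, L)], 0)
  }
  sums <- interp(edges[-1]) - interp(edges[-(n_bins + 1L)])
  sums / (L / n_bins)
}

#' Exon-scaled metagene profile
#'
#' Exonic signal is linearly rebinned to `exon_bins` positions; the
#' adjacent `flank` nt of intronic sequence on each side are aggregated
#' at natural per-nucleotide scale, measured from the exon edge in
#' transcription direction. Minus-strand regions are reversed so
#' position 1 is always 5'. Flank positions that run off the chromosome
#' are excluded from the mean at those positions.
#'
#' @param track combined, capped RleList.
#' @param regions exon interval table (chrom, start, end, strand).
#' @param exon_bins number of scaled exon bins (default 100).
#' @param flank flank length in nt (default 300).
#' @return data.table segment ("upstream"/"exon"/"downstream"), position
#'   (1-based within segment), mean_signal, n (regions contributing).
#' @export
metagene_profile <- function(track, regions, exon_bins = 100L,
                             flank = 300L) {
  regions <- as.data.table(regions)
  if (!nrow(regions)) stop("empty region group")
  up <- matrix(NA_real_, nrow(regions), flank)
  ex <- matrix(NA_real_, nrow(regions), exon_bins)
  dn <- matrix(NA_real_, nrow(regions), flank)
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i]
    ev <- .track_window(track, rg$chrom, rg$start, rg$end)
    left <- .track_window(track, rg$chrom, rg$start - flank, rg$start)
    right <- .track_window(track, rg$chrom, rg$end, rg$end + flank)
    if (identical(rg$strand, "-")) {
      ev <- rev(ev)
      tmp <- rev(right); right <- rev(left); left <- tmp
    }
    up[i, ] <- left
    ex[i, ] <- .rebin(ifelse(is.na(ev), 0, ev), exon_bins)
    dn[i, ] <- right
  }
  seg_dt <- function(m, seg) data.table(
    segment = seg, position = seq_len(ncol(m)),
    mean_signal = colMeans(m, na.rm = TRUE),
    n = colSums(!is.na(m)))
  rbindlist(list(seg_dt(up, "upstream"), seg_dt(ex, "exon"),
                 seg_dt(dn, "downstream")))
}
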