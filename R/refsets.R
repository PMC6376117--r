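# Matched reference sets: the controls every comparison in the package is
# made against. All constructions are pure functions of
# (pool, targets, seed) and record the seed and achieved-vs-target summary.

#' Cell-specific gene set (expressed genes)
#'
#' Genes detected at a mean FPKM at or above `threshold` in the cell
#' type's samples.
#'
#' @param expr output of [compute_fpkm()].
#' @param samples sample_ids of the cell type (default all).
#' @param threshold inclusive FPKM cutoff (default 1).
#' @return character vector of gene symbols.
#' @export
build_cell_specific <- function(expr, samples = NULL, threshold = 1) {
  expressed_genes(expr, samples, threshold)
}

#' Non-circRNA-producing gene set
#'
#' Expressed genes minus the genes producing back-spliced junctions.
#'
#' @param expressed character vector of expressed gene symbols.
#' @param circ_genes character vector of circRNA-producing gene symbols.
#' @return character vector (set difference).
#' @export
build_non_circ <- function(expressed, circ_genes) {
  out <- setdiff(expressed, circ_genes)
  if (!length(out) && length(expressed))
    warning("all expressed genes produce back-spliced junctions; ",
            "non-circ set is empty")
  out
}

#' Property-matched random gene sample
#'
#' Draws, for each target value, the pool member nearest in the matched
#' property (exon count, gene length or expression), without replacement,
#' ties broken by a seeded shuffle. This realises "randomly selected to
#' match" reproducibly: the achieved summary is reported next to the
#' target.
#'
#' @param pool named numeric vector: property value per candidate gene.
#' @param targets numeric vector of property values to match (the circ
#'   genes' values); the result has `length(targets)` members.
#' @param seed integer seed controlling tie-breaking.
#' @return object of class `matched_set`: list with `members`,
#'   `matched_property`, `targets`, `achieved_mean`, `target_mean`, `seed`.
#' @export
matched_sample <- function(pool, targets, seed = 1L) {
  if (!length(targets)) stop("no target values supplied")
  if (length(pool) < length(targets))
    stop("pool (", length(pool), ") smaller than targets (", length(targets),
         "); consider sampling with replacement")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample.int(length(pool))   # seeded shuffle for tie-breaking
  pool_v <- pool[ord]
  avail <- rep(TRUE, length(pool_v))
  members <- character(length(targets))
  props <- numeric(length(targets))
  for (i in seq_along(targets)) {
    d <- abs(pool_v - targets[i])
    d[!avail] <- Inf
    j <- which.min(d)              # first in shuffled order on ties
    members[i] <- names(pool_v)[j]
    props[i] <- pool_v[[j]]
    avail[j] <- FALSE
  }
  structure(list(members = members, matched_property = props,
                 targets = targets, achieved_mean = mean(props),
                 target_mean = mean(targets), seed = seed),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat("matched_set:", length(x$members), "members (seed", x$seed, ")\n",
      "  target mean ", signif(x$target_mean, 5),
      ", achieved mean ", signif(x$achieved_mean, 5), "\n", sep = "")
  invisible(x)
}

#' Largest-remainder allocation of n draws over a probability vector
#' @keywords internal
largest_remainder <- function(probs, n) {
  raw <- probs / sum(probs) * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Position-adjusted feature sample
#'
#' Samples pool features so that the empirical ordinal-position
#' distribution matches the target within one feature per position:
#' per-position counts come from largest-remainder allocation of
#' `n` over the target masses, then features are drawn without replacement
#' within each position under the seed.
#'
#' @param pool data.table with columns `feature_id` and `ordinal`.
#' @param target_dist named numeric vector: probability mass per ordinal
#'   position (names are positions); must sum to 1.
#' @param n number of features to draw.
#' @param seed integer seed.
#' @return `matched_set` with `members` (feature_ids), `positions`,
#'   `allocation` (position -> count) and `seed`.
#' @export
position_adjusted_sample <- function(pool, target_dist, n, seed = 1L) {
  pool <- as.data.table(pool)
  if (abs(sum(target_dist) - 1) > 1e-6)
    stop("target distribution must sum to 1")
  positions <- as.integer(names(target_dist))
  alloc <- largest_remainder(target_dist, n)
  names(alloc) <- names(target_dist)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  members <- character(0); mem_pos <- integer(0)
  for (k in seq_along(positions)) {
    if (alloc[k] == 0L) next
    cand <- pool[ordinal == positions[k], feature_id]
    if (!length(cand))
      stop("pool has no features at ordinal position ", positions[k])
    if (length(cand) < alloc[k])
      stop("pool exhausted at ordinal position ", positions[k], ": need ",
           alloc[k], ", have ", length(cand))
    take <- sample(cand, alloc[k])
    members <- c(members, take)
    mem_pos <- c(mem_pos, rep(positions[k], alloc[k]))
  }
  structure(list(members = members, positions = mem_pos,
                 allocation = alloc, target = target_dist, seed = seed),
            class = "matched_set")
}

# save/restore the global RNG state so seeded constructions do not
# perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
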