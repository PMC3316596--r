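#' Confusion counts over unordered gene pairs
#'
#' Classifies every unordered gene pair of the universe against a
#' ground-truth network: `tp` pairs are edges of both networks, `fp`
#' inferred-only, `fn` truth-only, `tn` the remainder. The counts always
#' sum to `choose(length(universe), 2)`.
#'
#' @param inferred,truth undirected igraph networks.
#' @param universe gene labels; defaults to the union of both vertex sets
#'   (isolated/unconnected genes included — they contribute tn/fp pairs).
#' @return named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusionCounts <- function(inferred, truth, universe = NULL) {
  if (is.null(universe))
    universe <- union(igraph::V(inferred)$name, igraph::V(truth)$name)
  if (!all(igraph::V(inferred)$name %in% universe) ||
      !all(igraph::V(truth)$name %in% universe))
    stop("network vertices must be contained in the universe")
  ei <- .edgeKeys(inferred)
  et <- .edgeKeys(truth)
  tp <- length(intersect(ei, et))
  fp <- length(ei) - tp
  fn <- length(et) - tp
  total <- choose(length(universe), 2)
  c(tp = tp, fp = fp, fn = fn, tn = as.integer(total - tp - fp - fn))
}

#' F-score of an inferred network
#'
#' Harmonic mean of precision `tp/(tp+fp)` and recall `tp/(tp+fn)`.
#' Degenerate cases (`tp = 0`) return 0.
#'
#' @param counts confusion counts as returned by [confusionCounts()] (a
#'   vector with named elements `tp`, `fp`, `fn`).
#' @return F-score in `[0, 1]`.
#' @examples
#' fScore(c(tp = 1, fp = 1, fn = 2, tn = 2))   # 0.4
#' @export
fScore <- function(counts) {
  tp <- counts[["tp"]]
  if (tp == 0) return(0)
  prec <- tp / (tp + counts[["fp"]])
  rec <- tp / (tp + counts[["fn"]])
  2 * prec * rec / (prec + rec)
}

#' Percent gain in true positives of one method over another
#'
#' `100 * (a - b) / max(b, 1)`: the percentage increase of true-positive
#' edges of method A over method B, with a unit floor in the denominator
#' so the degenerate `b = 0` case stays finite.
#'
#' @param methodATp,methodBTp true-positive counts of the two methods.
#' @return gain in percent.
#' @export
tpGain <- function(methodATp, methodBTp) {
  if (any(methodBTp < 0)) stop("true-positive counts must be nonnegative")
  100 * (methodATp - methodBTp) / pmax(methodBTp, 1)
}

#' Random-edge-set F-score baseline
#'
#' F-scores of uniformly random edge sets of a given size against the
#' truth network, giving an impression of the F-score achievable by
#' chance.
#'
#' @param truth undirected igraph truth network.
#' @param universe gene labels (default: truth vertices).
#' @param nEdges number of random edges per replicate, at most
#'   `choose(length(universe), 2)`.
#' @param nReps number of replicates, default 100.
#' @param seed optional integer seed.
#' @return numeric vector of `nReps` F-scores.
#' @export
randomBaseline <- function(truth, universe = NULL, nEdges, nReps = 100L,
                           seed = NULL) {
  if (is.null(universe)) universe <- igraph::V(truth)$name
  N <- length(universe)
  total <- N * (N - 1) / 2
  nEdges <- as.integer(nEdges)
  if (nEdges > total) stop("nEdges exceeds the number of gene pairs")
  .setSeed(seed)
  et <- .edgeKeys(truth)
  fn0 <- length(et)
  vapply(seq_len(nReps), function(r) {
    if (nEdges == 0L) return(0)
    ij <- .pairFromIndex(sample.int(total, nEdges), N)
    keys <- .pairKey(universe[ij[, 1L]], universe[ij[, 2L]])
    tp <- sum(keys %in% et)
    fScore(c(tp = tp, fp = nEdges - tp, fn = fn0 - tp))
  }, numeric(1))
}
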