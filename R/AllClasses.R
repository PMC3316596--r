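#' @import methods
NULL

#' Empirical null distribution of mutual information values
#'
#' Container for an empirical null distribution of MI values obtained by
#' randomizing an expression matrix under one of three schemes (RM1, RM2,
#' RM3). The null is used to attach a p-value to an observed MI value via
#' its upper tail (see [miPvalue()]).
#'
#' @slot values sorted (ascending) numeric vector of MI draws under the null,
#'   in nats.
#' @slot scheme randomization scheme, one of `"RM1"`, `"RM2"`, `"RM3"`.
#' @slot nDraws number of draws, `length(values)`.
#' @slot estimator identifier of the MI estimator that produced the draws.
#'
#' @seealso [buildMINull()], [miPvalue()]
#' @export
setClass("MINull",
  representation(values = "numeric", scheme = "character",
                 nDraws = "integer", estimator = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@values) != object@nDraws)
      msg <- c(msg, "length(values) must equal nDraws")
    if (is.unsorted(object@values))
      msg <- c(msg, "values must be sorted ascending")
    if (!object@scheme %in% c("RM1", "RM2", "RM3"))
      msg <- c(msg, "scheme must be RM1, RM2 or RM3")
    if (is.null(msg)) TRUE else msg
  }
)

#' Result of a bagged C3NET (BC3NET) inference run
#'
#' Holds the final Bonferroni-controlled network together with the
#' intermediate quantities of the bagging procedure: the ensemble
#' edge-frequency aggregate, the per-pair binomial test results, and the
#' estimated chance-edge probability.
#'
#' @slot network final binary undirected [igraph][igraph::graph] network;
#'   edges carry a `weight` attribute equal to their bootstrap frequency.
#' @slot aggregate symmetric integer matrix of bootstrap edge frequencies
#'   over all genes (values in `0..B`, zero diagonal).
#' @slot edgeStats data.frame with one row per gene pair observed in at
#'   least one ensemble member: `gene1`, `gene2`, `weight`, `pValue`,
#'   `adjPValue`, `significant`.
#' @slot pHat estimated probability that a gene pair is connected by chance
#'   in one ensemble member.
#' @slot eRand number of edges inferred from randomized data across the
#'   ensemble used to estimate `pHat`.
#' @slot mMax maximal number of gene pairs over the ensemble,
#'   `B * choose(n, 2)`.
#' @slot B bootstrap ensemble size.
#' @slot alpha significance level of the binomial test after correction.
#' @slot params list echoing the remaining configuration (estimator,
#'   randomization scheme, MTC, seeds, ...).
#'
#' @seealso [bc3net()], [inferredNetwork()], [edgeWeights()], [edgeStats()],
#'   [nullEdgeProb()]
#' @export
setClass("BC3Net",
  representation(network = "ANY", aggregate = "matrix",
                 edgeStats = "data.frame", pHat = "numeric",
                 eRand = "numeric", mMax = "numeric", B = "integer",
                 alpha = "numeric", params = "list"),
  validity = function(object) {
    msg <- NULL
    w <- object@aggregate
    if (nrow(w) != ncol(w) || !isTRUE(all.equal(w, t(w))))
      msg <- c(msg, "aggregate must be a symmetric matrix")
    if (any(w < 0) || any(w > object@B))
      msg <- c(msg, "aggregate weights must lie in [0, B]")
    if (any(diag(w) != 0))
      msg <- c(msg, "aggregate diagonal must be zero")
    if (object@pHat <= 0 || object@pHat >= 1)
      msg <- c(msg, "pHat must lie strictly in (0, 1)")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn MINull number of draws and summary quantiles.
#' @param object a `MINull` or `BC3Net` object.
#' @export
setMethod("show", "MINull", function(object) {
  cat("MINull:", object@nDraws, "draws under", object@scheme,
      "| estimator:", object@estimator, "\n")
  q <- stats::quantile(object@values, c(0.5, 0.95, 0.99))
  cat(sprintf("  median %.4g | q95 %.4g | q99 %.4g nats\n", q[1], q[2], q[3]))
})

#' @describeIn BC3Net one-screen summary of the run.
#' @param object a `BC3Net` object.
#' @export
setMethod("show", "BC3Net", function(object) {
  g <- object@network
  cat("BC3Net result:", igraph::vcount(g), "genes,",
      igraph::ecount(g), "significant edges\n")
  cat(sprintf("  ensemble B = %d | pHat = %.3g (eRand = %g of mMax = %g)\n",
              object@B, object@pHat, object@eRand, object@mMax))
  cat(sprintf("  alpha = %g, MTC = %s | estimator = %s, null scheme = %s\n",
              object@alpha, object@params$mtc, object@params$estimator,
              object@params$scheme))
})

#' Accessors for BC3Net results
#'
#' @param x a [BC3Net-class] object.
#' @return `inferredNetwork()` the final igraph network; `edgeWeights()` the
#'   symmetric bootstrap edge-frequency matrix; `edgeStats()` the per-pair
#'   binomial test table; `nullEdgeProb()` a named list with the chance-edge
#'   probability estimate (`pHat`, `eRand`, `mMax`).
#' @name BC3Net-accessors
NULL

#' @rdname BC3Net-accessors
#' @export
inferredNetwork <- function(x) {
  stopifnot(is(x, "BC3Net"))
  x@network
}

#' @rdname BC3Net-accessors
#' @export
edgeWeights <- function(x) {
  stopifnot(is(x, "BC3Net"))
  x@aggregate
}

#' @rdname BC3Net-accessors
#' @export
edgeStats <- function(x) {
  stopifnot(is(x, "BC3Net"))
  x@edgeStats
}

#' @rdname BC3Net-accessors
#' @export
nullEdgeProb <- function(x) {
  stopifnot(is(x, "BC3Net"))
  list(pHat = x@pHat, eRand = x@eRand, mMax = x@mMax)
}

#' @describeIn MINull the sorted vector of null MI draws.
#' @param x a `MINull` object.
#' @export
nullValues <- function(x) {
  stopifnot(is(x, "MINull"))
  x@values
}
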