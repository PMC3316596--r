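#' Non-parametric bootstrap resample of an expression matrix
#'
#' Draws samples (columns) uniformly with replacement, preserving the
#' number of samples and all gene rows.
#'
#' @param data genes x samples numeric matrix.
#' @param seed optional integer seed.
#' @return a matrix of identical dimensions whose columns are columns of
#'   the input.
#' @export
bootstrapResample <- function(data, seed = NULL) {
  data <- .exprMatrix(data)
  if (ncol(data) < 2L) stop("need at least two samples")
  .setSeed(seed)
  data[, sample.int(ncol(data), replace = TRUE), drop = FALSE]
}

#' Aggregate an ensemble of networks into edge frequencies
#'
#' Counts, for every unordered gene pair, the number of ensemble member
#' networks containing that edge.
#'
#' @param networks list of undirected igraph networks (the ensemble).
#' @param geneUniverse character vector of gene labels; every network's
#'   vertices must be a subset.
#' @return symmetric integer matrix over `geneUniverse` with zero
#'   diagonal and values in `0..length(networks)`; the ensemble size is
#'   recorded in `attr(, "B")`.
#' @export
aggregateNetworks <- function(networks, geneUniverse) {
  if (!length(networks)) stop("empty ensemble")
  W <- matrix(0L, length(geneUniverse), length(geneUniverse),
              dimnames = list(geneUniverse, geneUniverse))
  for (g in networks) {
    nm <- igraph::V(g)$name
    if (!all(nm %in% geneUniverse))
      stop("network contains genes outside the gene universe")
    if (igraph::ecount(g) == 0L) next
    el <- igraph::as_edgelist(g, names = TRUE)
    W[el] <- W[el] + 1L
    W[el[, c(2L, 1L), drop = FALSE]] <- W[el[, c(2L, 1L), drop = FALSE]] + 1L
  }
  diag(W) <- 0L
  attr(W, "B") <- length(networks)
  W
}

#' Estimate the chance-edge probability of the bootstrap ensemble
#'
#' Estimates `p`, the probability that a gene pair is connected by chance
#' in one ensemble member: the full matrix is randomized (RM3), a
#' bootstrap ensemble of size `B` is generated from the randomized matrix,
#' C3NET (without its own multiple-testing correction) is run on every
#' member, and the total number of inferred edges `eRand` is divided by
#' the maximal number of gene pairs `mMax = B * choose(n, 2)`. A +1/+1
#' pseudocount keeps the estimate strictly inside (0, 1) even when no
#' random edge is found.
#'
#' @inheritParams c3net
#' @param B ensemble size.
#' @param nRandomizations number of independent matrix randomizations to
#'   average `eRand` over (default 1).
#' @param sharedNull reuse one MI null (built from the randomized matrix)
#'   across the ensemble members of a randomization (default `TRUE`).
#' @param memberMtc multiple-testing correction used inside the member
#'   C3NET runs; must match the setting of the observed ensemble for the
#'   estimate to be calibrated (see [bc3net()]).
#' @return list with `pHat = (eRand + 1) / (mMax + 1)`, `eRand` (averaged
#'   and rounded) and `mMax`.
#' @export
estimateNullEdgeProb <- function(data, B = 100L, alpha = 0.05,
                                 estimator = "bspline", scheme = "RM3",
                                 nDraws = 10000L, nRandomizations = 1L,
                                 sharedNull = TRUE,
                                 memberMtc = c("bonferroni", "none"),
                                 seed = NULL, nBins = NULL, order = 3L,
                                 method = "equal-width") {
  memberMtc <- match.arg(memberMtc)
  data <- .exprMatrix(data)
  B <- as.integer(B)
  G <- nrow(data)
  .setSeed(seed)
  tot <- numeric(nRandomizations)
  for (r in seq_len(nRandomizations)) {
    rd <- randomizeExpression(data, scheme = "RM3")
    null <- if (sharedNull)
      buildMINull(rd, scheme = scheme, estimator = estimator,
                  nDraws = nDraws, bootstrap = TRUE, nBins = nBins,
                  order = order, method = method)
    else NULL
    edges <- 0L
    for (b in seq_len(B)) {
      db <- bootstrapResample(rd)
      gb <- c3net(db, estimator = estimator, scheme = scheme,
                  alpha = alpha, mtc = memberMtc, nDraws = nDraws,
                  null = null, nBins = nBins, order = order,
                  method = method)
      edges <- edges + igraph::ecount(gb)
    }
    tot[r] <- edges
  }
  eRand <- round(mean(tot))
  mMax <- B * G * (G - 1) / 2
  list(pHat = (eRand + 1) / (mMax + 1), eRand = eRand, mMax = mMax)
}

#' Binomial p-value for a bootstrap edge frequency
#'
#' Probability of observing `k` or more occurrences of an edge in a
#' bootstrap ensemble of size `B` when edges arise independently by chance
#' with probability `p`: the upper tail `P(X >= k)` of `Binomial(B, p)`.
#'
#' @param k observed edge frequency (vectorized), `0 <= k <= B`.
#' @param B ensemble size.
#' @param p chance-edge probability in (0, 1).
#' @return p-values in `(0, 1]`; `k = 0` gives exactly 1.
#' @examples
#' edgePvalue(2, 3, 0.5)       # 0.5
#' edgePvalue(1, 10, 0.1)      # 1 - 0.9^10
#' @export
edgePvalue <- function(k, B, p) {
  if (any(k < 0) || any(k > B)) stop("k must lie in [0, B]")
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  stats::pbinom(k - 1, size = B, prob = p, lower.tail = FALSE)
}

#' BC3NET: bagged C3NET network inference
#'
#' Infers a gene regulatory network by bootstrap aggregation of C3NET.
#' `B` bootstrap datasets are drawn from the expression matrix; the full
#' C3NET algorithm (including its own Bonferroni step, see `memberMtc`)
#' is run on each; the resulting ensemble is aggregated into edge
#' frequencies; the chance-edge probability is estimated from randomized
#' data by the same ensemble procedure; every gene pair observed in the
#' ensemble is tested against the binomial null `Binomial(B, pHat)`; and
#' the correction over all `n(n-1)/2` pair hypotheses (Bonferroni by
#' default) yields the final binary undirected network. Pairs never
#' observed in the ensemble have p-value 1 by construction but still
#' count toward the correction denominator.
#'
#' `memberMtc = "none"` runs the members at the uncorrected per-test
#' `alpha` instead. This admits many spurious member edges, and because a
#' dataset's top-ranked noise pairs persist across bootstrap resamples
#' (the binomial null only calibrates the *rate* of chance edges, not
#' their concentration on recurrent pairs), the final network then loses
#' its family-wise error control under the global null. The bagged-full-
#' C3NET default keeps it.
#'
#' The empirical MI null must be able to resolve the member-level
#' rejection threshold: with `memberMtc = "bonferroni"` a member edge
#' needs a pairwise tail probability below roughly
#' `alpha / (n (n-1))`, so `nDraws` should exceed `n (n-1) / alpha`
#' (e.g. 2e5 for 100 genes at `alpha = 0.05`); with a coarser null the
#' members — and hence the ensemble — are simply empty.
#'
#' @inheritParams estimateNullEdgeProb
#' @param mtc multiple-testing correction over gene pairs:
#'   `"bonferroni"` (default, family-wise error control), `"bh"`
#'   (Benjamini-Hochberg FDR) or `"none"`.
#' @param sharedNull build one MI null from the original data's RM3
#'   randomization and reuse it across all `B` member runs (default);
#'   `FALSE` builds a null per bootstrap dataset.
#' @param seed integer seed; fans out into independent sub-streams for the
#'   null, the bootstrap and the chance-edge estimation, so each stage is
#'   reproducible on its own.
#' @param verbose print progress and the estimated `pHat`.
#' @return a [BC3Net-class] object.
#' @seealso [c3net()], [edgePvalue()], [estimateNullEdgeProb()]
#' @export
bc3net <- function(data, B = 100L, alpha = 0.05,
                   mtc = c("bonferroni", "bh", "none"),
                   estimator = "bspline", scheme = "RM3", nDraws = 10000L,
                   nRandomizations = 1L, sharedNull = TRUE,
                   memberMtc = c("bonferroni", "none"), seed = NULL,
                   verbose = FALSE, nBins = NULL, order = 3L,
                   method = "equal-width") {
  mtc <- match.arg(mtc)
  memberMtc <- match.arg(memberMtc)
  data <- .exprMatrix(data)
  B <- as.integer(B)
  if (B < 2L) stop("ensemble size B must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  G <- nrow(data)
  if (G < 3L || ncol(data) < 3L) stop("need at least 3 genes and 3 samples")
  genes <- rownames(data)

  null <- NULL
  if (sharedNull) {
    # the shared null must mirror the member-run conditions: members see
    # bootstrap resamples, so the null draws do too
    .setSeed(.deriveSeed(seed, "null"))
    null <- buildMINull(data, scheme = scheme, estimator = estimator,
                        nDraws = nDraws, bootstrap = TRUE, nBins = nBins,
                        order = order, method = method)
  }

  .setSeed(.deriveSeed(seed, "bootstrap"))
  members <- vector("list", B)
  for (b in seq_len(B)) {
    db <- bootstrapResample(data)
    nb <- if (sharedNull) null
          else buildMINull(db, scheme = scheme, estimator = estimator,
                           nDraws = nDraws, nBins = nBins, order = order,
                           method = method)
    members[[b]] <- c3net(db, estimator = estimator, scheme = scheme,
                          alpha = alpha, mtc = memberMtc, nDraws = nDraws,
                          null = nb, nBins = nBins, order = order,
                          method = method)
    if (verbose && b %% 10L == 0L) message("bootstrap ", b, "/", B)
  }
  W <- aggregateNetworks(members, genes)

  est <- estimateNullEdgeProb(data, B = B, alpha = alpha,
                              estimator = estimator, scheme = scheme,
                              nDraws = nDraws,
                              nRandomizations = nRandomizations,
                              sharedNull = sharedNull,
                              memberMtc = memberMtc,
                              seed = .deriveSeed(seed, "phat"),
                              nBins = nBins, order = order, method = method)
  if (verbose)
    message(sprintf("pHat = %.4g (eRand = %g / mMax = %g)",
                    est$pHat, est$eRand, est$mMax))

  ut <- upper.tri(W)
  pos <- which(ut & W > 0, arr.ind = TRUE)
  npairs <- G * (G - 1) / 2
  stats <- data.frame(gene1 = genes[pos[, 1L]], gene2 = genes[pos[, 2L]],
                      weight = W[pos], stringsAsFactors = FALSE)
  if (nrow(stats)) {
    stats$pValue <- edgePvalue(stats$weight, B, est$pHat)
    stats$adjPValue <- switch(mtc,
      bonferroni = pmin(1, stats$pValue * npairs),
      bh = {
        # BH over all n(n-1)/2 hypotheses; unobserved pairs enter as p = 1
        full <- c(stats$pValue, rep(1, npairs - nrow(stats)))
        stats::p.adjust(full, method = "BH")[seq_len(nrow(stats))]
      },
      none = stats$pValue)
    stats$significant <- stats$adjPValue < alpha
    stats <- stats[order(stats$pValue, -stats$weight), , drop = FALSE]
    rownames(stats) <- NULL
  } else {
    stats$pValue <- numeric(0)
    stats$adjPValue <- numeric(0)
    stats$significant <- logical(0)
  }

  sig <- stats[stats$significant, , drop = FALSE]
  net <- if (nrow(sig)) {
    d <- data.frame(from = sig$gene1, to = sig$gene2, weight = sig$weight,
                    pValue = sig$pValue, adjPValue = sig$adjPValue,
                    stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(d, directed = FALSE,
                                  vertices = data.frame(name = genes))
  } else {
    .edgesToGraph(character(0), numeric(0), numeric(0), genes)
  }

  methods::new("BC3Net", network = net, aggregate = `attr<-`(W, "B", NULL),
               edgeStats = stats, pHat = est$pHat,
               eRand = as.numeric(est$eRand), mMax = est$mMax, B = B,
               alpha = alpha,
               params = list(mtc = mtc, memberMtc = memberMtc,
                             estimator = estimator,
                             scheme = scheme, nDraws = nDraws,
                             nRandomizations = nRandomizations,
                             sharedNull = sharedNull, seed = seed,
                             nBins = nBins, order = order,
                             method = method))
}
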