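#' Randomize an expression matrix under a null scheme
#'
#' Produces a permuted-matrix surrogate for the null hypothesis of zero
#' mutual information between gene profiles, under one of three schemes:
#'
#' * `RM1` — each gene's samples are permuted independently, so the sample
#'   correspondence between any two profiles is destroyed while every
#'   profile keeps its own value multiset.
#' * `RM2` — as RM1, but additionally the gene rows are reassigned at
#'   random (sample and gene labels permuted per pair).
#' * `RM3` — all values of the matrix are permuted at once across cells
#'   (sample and gene labels of the entire matrix), the computationally
#'   cheapest scheme.
#'
#' [buildMINull()] uses these schemes with their exact per-pair draw
#' semantics; this function exposes the matrix-level randomization.
#'
#' @param data genes x samples numeric matrix.
#' @param scheme `"RM3"` (default), `"RM1"` or `"RM2"`.
#' @param seed optional integer seed.
#' @return a randomized matrix with the same dimensions and dimnames.
#' @export
randomizeExpression <- function(data, scheme = c("RM3", "RM1", "RM2"),
                                seed = NULL) {
  scheme <- match.arg(scheme)
  data <- .exprMatrix(data)
  .setSeed(seed)
  out <- switch(scheme,
    RM3 = matrix(sample(data), nrow(data), ncol(data)),
    RM1 = t(apply(data, 1L, sample)),
    RM2 = {
      m <- data[sample(nrow(data)), , drop = FALSE]
      t(apply(m, 1L, sample))
    })
  dimnames(out) <- dimnames(data)
  out
}

#' Build an empirical MI null distribution
#'
#' Draws `nDraws` mutual information values between randomized profile
#' pairs, giving the null distribution for the hypothesis that the MI of a
#' gene pair is zero. Under RM1 each draw permutes one profile of a random
#' gene pair; under RM2 both profiles come from randomly chosen rows and
#' are permuted; under RM3 the whole matrix is permuted at once and MI is
#' evaluated on distinct pairs of the randomized matrix (the matrix is
#' re-randomized whenever the distinct pairs of one round are exhausted).
#'
#' When the null is consumed by tests on *bootstrap resamples* of the
#' data (as inside [bc3net()]'s ensemble), set `bootstrap = TRUE`: each
#' randomization round is then itself bootstrap-resampled before MI is
#' drawn, so the null reflects the duplicated-sample structure (smaller
#' effective sample size, hence inflated MI values) of the data actually
#' being tested. A null built from un-resampled data sits systematically
#' below bootstrap MI values and makes downstream tests anti-conservative.
#'
#' @inheritParams randomizeExpression
#' @param estimator,nBins,order,method MI estimator configuration, see
#'   [miMatrix()].
#' @param nDraws number of null draws, at least 100.
#' @param bootstrap draw the null from bootstrap-resampled randomized
#'   data (default `FALSE`), see Details.
#' @return a [MINull-class] object with the draws sorted ascending.
#' @export
buildMINull <- function(data, scheme = c("RM3", "RM1", "RM2"),
                        estimator = "bspline", nDraws = 10000L, seed = NULL,
                        bootstrap = FALSE, nBins = NULL, order = 3L,
                        method = "equal-width") {
  scheme <- match.arg(scheme)
  data <- .exprMatrix(data)
  nDraws <- as.integer(nDraws)
  if (nDraws < 100L) stop("nDraws must be at least 100")
  G <- nrow(data)
  n <- ncol(data)
  if (G < 2L) stop("need at least two genes")
  .setSeed(seed)
  eng <- .miEngine(estimator, n, nBins = nBins, order = order,
                   method = method)
  vals <- numeric(nDraws)
  if (scheme == "RM3") {
    npairs <- G * (G - 1L) / 2
    done <- 0L
    fastCor <- estimator %in% c("pearson", "spearman")
    while (done < nDraws) {
      rd <- matrix(sample(data), G, n)
      if (bootstrap) rd <- rd[, sample.int(n, replace = TRUE), drop = FALSE]
      take <- min(nDraws - done, npairs)
      pick <- if (take == npairs) seq_len(npairs)
              else sample.int(npairs, take)
      ij <- .pairFromIndex(pick, G)
      if (fastCor) {
        # one BLAS call per randomization round instead of per draw
        if (estimator == "spearman") rd <- t(apply(rd, 1L, rank))
        C <- suppressWarnings(stats::cor(t(rd)))
        C[!is.finite(C)] <- 0   # constant rows after resampling
        vals[done + seq_len(take)] <- .corToMI(C[ij])
      } else {
        reps <- vector("list", G)
        for (g in unique(c(ij))) reps[[g]] <- eng$prep(rd[g, ])
        for (d in seq_len(take)) {
          vals[done + d] <- eng$mi(reps[[ij[d, 1L]]], reps[[ij[d, 2L]]])
        }
      }
      done <- done + take
    }
  } else if (scheme == "RM1") {
    for (d in seq_len(nDraws)) {
      ij <- sample.int(G, 2L)
      idx <- if (bootstrap) sample.int(n, replace = TRUE) else seq_len(n)
      vals[d] <- eng$mi(eng$prep(data[ij[1L], idx]),
                        eng$prep(sample(data[ij[2L], idx])))
    }
  } else {
    for (d in seq_len(nDraws)) {
      ij <- sample.int(G, 2L, replace = TRUE)
      idx <- if (bootstrap) sample.int(n, replace = TRUE) else seq_len(n)
      vals[d] <- eng$mi(eng$prep(sample(data[ij[1L], idx])),
                        eng$prep(sample(data[ij[2L], idx])))
    }
  }
  methods::new("MINull", values = sort(vals), scheme = scheme,
               nDraws = nDraws, estimator = estimator)
}

# map linear indices 1..C(G,2) to (i, j) pairs with i < j
.pairFromIndex <- function(idx, G) {
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  cbind(as.integer(i), as.integer(j))
}

#' Empirical p-value of an observed MI value
#'
#' Upper-tail probability of an observed MI value under an empirical null,
#' with the standard permutation-test pseudocount:
#' `p = (r + 1) / (nDraws + 1)` where `r` counts null draws `>=` the
#' observation. Always strictly positive and at most 1.
#'
#' @param observed finite numeric vector of observed MI values.
#' @param null a [MINull-class] object or a numeric vector of null draws.
#' @return p-values in `(0, 1]`, one per observation.
#' @export
miPvalue <- function(observed, null) {
  v <- if (methods::is(null, "MINull")) null@values else sort(null)
  if (any(!is.finite(observed))) stop("observed MI must be finite")
  nd <- length(v)
  r <- nd - findInterval(observed, v, left.open = TRUE)
  (r + 1) / (nd + 1)
}

#' C3NET: conservative causal core network inference
#'
#' The base inference algorithm: (1) the MI matrix over all gene pairs is
#' computed; (2) each gene nominates its maximum-MI partner, so at most `n`
#' candidate edges (and `n` hypotheses) arise; (3) each candidate's MI is
#' tested against the empirical null; (4) multiple-testing correction over
#' the `n` tests; (5) the network is the union of significant candidate
#' pairs (an edge is kept when significant from either endpoint).
#'
#' `ordering = "filter-first"` exposes the alternative formulation in which
#' all `n(n-1)/2` pair MIs are tested (and corrected) first and each gene
#' then picks its maximal *significant* partner.
#'
#' A gene's candidate is the *maximum* over its `n - 1` pairwise MI
#' values, so its calibrated p-value is the upper tail of the null of that
#' maximum. With `candidateNull = "max"` (default) this is obtained from
#' the pairwise empirical p-value `p` by the Sidak transform
#' `1 - (1 - p)^(n-1)`; only then does Bonferroni over the `n` candidate
#' tests control the family-wise error rate under the global null.
#' `candidateNull = "pairwise"` uses the uncorrected pairwise p-value (the
#' candidate's MI compared directly against the single-pair null), which
#' is anti-conservative for the maximum statistic.
#'
#' @inheritParams miMatrix
#' @param scheme randomization scheme for the MI null, see
#'   [randomizeExpression()].
#' @param alpha significance level, in (0, 1).
#' @param mtc `"bonferroni"` (default) or `"none"`.
#' @param nDraws null-distribution size, see [buildMINull()].
#' @param seed optional integer seed (null construction).
#' @param null optional precomputed [MINull-class], bypassing construction.
#' @param mim optional precomputed MI matrix, bypassing [miMatrix()].
#' @param ordering `"select-first"` (default; test the n candidate edges)
#'   or `"filter-first"` (test all pairs, then select).
#' @param candidateNull `"max"` (default) or `"pairwise"`, see Details;
#'   only used with `ordering = "select-first"`.
#' @return an undirected [igraph][igraph::graph] over all genes (isolated
#'   vertices kept); edges carry `mi` and `pValue` attributes. Ties in a
#'   gene's MI row are broken toward the lexicographically smallest partner
#'   label, so results are seed-independent given the null.
#' @export
c3net <- function(data, estimator = "bspline", scheme = "RM3", alpha = 0.05,
                  mtc = c("bonferroni", "none"), nDraws = 10000L,
                  seed = NULL, null = NULL, mim = NULL,
                  ordering = c("select-first", "filter-first"),
                  candidateNull = c("max", "pairwise"),
                  nBins = NULL, order = 3L, method = "equal-width") {
  mtc <- match.arg(mtc)
  ordering <- match.arg(ordering)
  candidateNull <- match.arg(candidateNull)
  data <- .exprMatrix(data)
  G <- nrow(data)
  if (G < 3L) stop("need at least three genes")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(mim))
    mim <- miMatrix(data, estimator = estimator, nBins = nBins,
                    order = order, method = method)
  if (is.null(null))
    null <- buildMINull(data, scheme = scheme, estimator = estimator,
                        nDraws = nDraws, seed = seed, nBins = nBins,
                        order = order, method = method)
  genes <- rownames(data)
  ord <- order(genes)   # column scan order for lexicographic tie-breaks
  edges <- character(0)
  edgeMI <- numeric(0)
  edgeP <- numeric(0)
  if (ordering == "select-first") {
    partner <- integer(G)
    cand <- numeric(G)
    for (i in seq_len(G)) {
      row <- mim[i, ord]
      row[ord == i] <- -Inf
      best <- which.max(row)            # first max in label order
      partner[i] <- ord[best]
      cand[i] <- row[best]
    }
    p <- miPvalue(cand, null)
    if (candidateNull == "max") p <- 1 - (1 - p)^(G - 1)
    padj <- if (mtc == "bonferroni") pmin(1, p * G) else p
    keep <- which(padj < alpha & cand > -Inf)
    if (length(keep)) {
      key <- .pairKey(genes[keep], genes[partner[keep]])
      first <- !duplicated(key)
      edges <- key[first]
      edgeMI <- cand[keep][first]
      edgeP <- p[keep][first]
    }
  } else {
    pr <- .allPairs(genes)
    miv <- mim[cbind(pr$gene1, pr$gene2)]
    p <- miPvalue(miv, null)
    npairs <- nrow(pr)
    padj <- if (mtc == "bonferroni") pmin(1, p * npairs) else p
    sig <- padj < alpha
    mSig <- mim
    mSig[] <- -Inf
    ok <- which(sig)
    if (length(ok)) {
      mSig[cbind(pr$gene1[ok], pr$gene2[ok])] <- miv[ok]
      mSig[cbind(pr$gene2[ok], pr$gene1[ok])] <- miv[ok]
      keys <- character(0)
      for (i in seq_len(G)) {
        row <- mSig[i, ord]
        row[ord == i] <- -Inf
        if (all(row == -Inf)) next
        best <- which.max(row)
        keys <- c(keys, .pairKey(genes[i], genes[ord[best]]))
      }
      if (length(keys)) {
        edges <- unique(keys)
        gp <- do.call(rbind, strsplit(edges, "\r", fixed = TRUE))
        edgeMI <- mim[cbind(gp[, 1L], gp[, 2L])]
        edgeP <- miPvalue(edgeMI, null)
      }
    }
  }
  .edgesToGraph(edges, edgeMI, edgeP, genes)
}

.edgesToGraph <- function(keys, mi, pValue, genes) {
  if (length(keys)) {
    gp <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    d <- data.frame(from = gp[, 1L], to = gp[, 2L], mi = mi,
                    pValue = pValue, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(d, directed = FALSE,
                                  vertices = data.frame(name = genes))
  } else {
    igraph::make_empty_graph(n = length(genes), directed = FALSE) |>
      igraph::set_vertex_attr("name", value = genes)
  }
}
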