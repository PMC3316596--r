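#' Erdős–Rényi ground-truth network
#'
#' Generates an undirected Erdős–Rényi random graph: starting from `n`
#' unconnected vertices, every vertex pair among the connectable genes is
#' joined independently with probability `edgeProbability`. A designated
#' set of `nUnconnected` genes receives no edges at all, mirroring
#' benchmark truths that contain genes without any regulatory interaction.
#'
#' @param n total number of genes.
#' @param edgeProbability per-pair edge probability in `[0, 1]`.
#' @param nUnconnected number of genes kept edge-free (`< n`), default 0.
#' @param seed optional integer seed.
#' @return an undirected igraph with `n` named vertices (`G001`, ...); the
#'   last `nUnconnected` are isolated.
#' @export
erdosRenyiNetwork <- function(n, edgeProbability, nUnconnected = 0L,
                              seed = NULL) {
  n <- as.integer(n)
  nUnconnected <- as.integer(nUnconnected)
  if (edgeProbability < 0 || edgeProbability > 1)
    stop("edgeProbability must lie in [0, 1]")
  if (nUnconnected < 0L || nUnconnected >= n)
    stop("nUnconnected must be in [0, n)")
  .setSeed(seed)
  g <- igraph::sample_gnp(n - nUnconnected, edgeProbability, directed = FALSE)
  g <- igraph::add_vertices(g, nUnconnected)
  igraph::V(g)$name <- sprintf("G%03d", seq_len(n))
  g
}

#' Sample a connected subnetwork from the giant connected component
#'
#' Grows a connected induced subgraph of the requested size by
#' breadth-first expansion from a random start vertex inside the giant
#' connected component (GCC) of the source network, e.g. a transcriptional
#' regulatory network supplied as an edge list.
#'
#' @param source undirected igraph network.
#' @param size number of vertices, at most the GCC size.
#' @param seed optional integer seed.
#' @return a connected induced subgraph with `size` vertices.
#' @export
sampleSubnetwork <- function(source, size, seed = NULL) {
  size <- as.integer(size)
  comp <- igraph::components(source)
  gccId <- which.max(comp$csize)
  gcc <- igraph::induced_subgraph(source,
                                  which(comp$membership == gccId))
  if (size > igraph::vcount(gcc))
    stop("size exceeds the giant connected component (",
         igraph::vcount(gcc), " vertices)")
  if (size < 1L) stop("size must be at least 1")
  .setSeed(seed)
  # permute vertex ids so BFS neighbor order is randomized, then take the
  # first `size` vertices in BFS order from a random start
  gcc <- igraph::permute(gcc, sample(igraph::vcount(gcc)))
  start <- sample.int(igraph::vcount(gcc), 1L)
  bfsOrder <- igraph::bfs(gcc, root = start, order = TRUE)$order
  igraph::induced_subgraph(gcc, bfsOrder[seq_len(size)])
}

# Hill response of a regulator activity a in (0, 1); K = half-saturation
.hill <- function(a, K, h) a^h / (K^h + a^h)

#' Simulate expression data from a ground-truth network
#'
#' Generates a genes x samples expression matrix whose statistical
#' dependence structure follows the wiring of `truth`. The undirected
#' truth network is given a random acyclic orientation; source genes draw
#' independent latent activities per sample; every downstream gene's
#' activity is a saturating Hill-type combination of its regulators'
#' activities (activation or repression with equal probability per edge);
#' and measured expression is the log2 abundance with additive Gaussian
#' noise of standard deviation `noiseSd` on the log scale (i.e.,
#' multiplicative log-normal noise on the raw scale), emulating normalized
#' microarray intensities with biological noise. Genes adjacent in the
#' truth network are statistically dependent; unconnected genes are
#' independent of every other gene.
#'
#' @param truth undirected igraph ground-truth network with named
#'   vertices.
#' @param nSamples number of samples (columns).
#' @param noiseSd log-scale noise standard deviation, default 0.1.
#' @param hillCoef Hill coefficient of the regulation kinetics, default 2.
#' @param seed optional integer seed.
#' @return genes x samples numeric matrix (log2 scale) with gene and
#'   sample dimnames.
#' @export
simulateExpression <- function(truth, nSamples, noiseSd = 0.1,
                               hillCoef = 2, seed = NULL) {
  nSamples <- as.integer(nSamples)
  if (nSamples < 1L) stop("nSamples must be positive")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  genes <- igraph::V(truth)$name
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(igraph::vcount(truth)))
  G <- length(genes)
  .setSeed(seed)
  # random acyclic orientation: direct every edge from the earlier to the
  # later gene of a random topological order
  topo <- sample.int(G)
  rank <- order(topo)   # rank[v] = position of v in the order
  el <- igraph::as_edgelist(truth, names = FALSE)
  if (nrow(el)) {
    flip <- rank[el[, 1L]] > rank[el[, 2L]]
    el[flip, ] <- el[flip, c(2L, 1L)]
  }
  parents <- vector("list", G)
  signs <- vector("list", G)
  if (nrow(el)) {
    sgn <- sample(c(1, -1), nrow(el), replace = TRUE)
    for (e in seq_len(nrow(el))) {
      ch <- el[e, 2L]
      parents[[ch]] <- c(parents[[ch]], el[e, 1L])
      signs[[ch]] <- c(signs[[ch]], sgn[e])
    }
  }
  act <- matrix(0, G, nSamples)
  for (v in topo) {   # topological order: parents precede children
    pa <- parents[[v]]
    if (is.null(pa)) {
      act[v, ] <- stats::runif(nSamples)
    } else {
      resp <- matrix(0, length(pa), nSamples)
      for (q in seq_along(pa)) {
        a <- act[pa[q], ]
        K <- mean(a)                 # half-saturation at mean activity
        if (K <= 0) K <- 0.5
        h <- .hill(a, K, hillCoef)
        resp[q, ] <- if (signs[[v]][q] > 0) h else 1 - h
      }
      act[v, ] <- colMeans(resp)
    }
  }
  # log2 abundance with a basal offset, plus Gaussian log-scale noise
  expr <- log2(0.1 + act) + 8
  if (noiseSd > 0)
    expr <- expr + matrix(stats::rnorm(G * nSamples, sd = noiseSd),
                          G, nSamples)
  dimnames(expr) <- list(genes, sprintf("S%03d", seq_len(nSamples)))
  expr
}
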