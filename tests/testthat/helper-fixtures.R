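# fixtures shared across test files; everything is generated in code

# iid Gaussian noise matrix (no dependence structure at all)
noiseMatrix <- function(nGenes, nSamples, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
              dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                              sprintf("S%03d", seq_len(nSamples))))
  m
}

# bivariate normal with given correlation
rhoPair <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  list(x = x, y = rho * x + sqrt(1 - rho^2) * rnorm(n))
}

# small undirected graph from an edge-list matrix over a gene universe
toyGraph <- function(edges, universe) {
  if (length(edges) == 0) {
    g <- igraph::make_empty_graph(length(universe), directed = FALSE)
    igraph::V(g)$name <- universe
    return(g)
  }
  d <- as.data.frame(matrix(edges, ncol = 2, byrow = TRUE),
                     stringsAsFactors = FALSE)
  names(d) <- c("from", "to")
  igraph::graph_from_data_frame(d, directed = FALSE,
                                vertices = data.frame(name = universe))
}

# canonical unordered pair keys of a graph, for set comparisons in tests
edgeSet <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}
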