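#' Gene-pair enrichment test for one gene set
#'
#' Tests whether a network's edges are over-represented among the gene
#' pairs of a gene set (e.g. a GO term): a hypergeometric (one-sided
#' Fisher) test over *edges* instead of genes. With `N` universe genes
#' there are `T = choose(N, 2)` possible pairs, of which
#' `M = choose(m, 2)` lie inside the term (`m` term genes in the
#' universe). Drawing the network's `E` edges from the `T` pairs, the
#' p-value is the upper tail `P(X >= k)` for the `k` edges observed with
#' both endpoints in the term. For terms describing protein complexes the
#' implicit clique null is apt; for broader categories it is conservative.
#'
#' @param network undirected igraph network.
#' @param termGenes character vector of the gene set's members.
#' @param universe gene labels (default: the network's vertices); network
#'   vertices must be contained in it.
#' @return one-row data.frame: `genes` (term genes in the universe),
#'   `edges` (k), `expected` (`M * E / T`), `pValue`.
#' @examples
#' g <- igraph::graph_from_literal(a - b, a - c, a - d, d - e)
#' gpeaTest(g, c("a", "b", "c"), letters[1:5])   # k = 2 of E = 4, p = 1/3
#' @export
gpeaTest <- function(network, termGenes, universe = NULL) {
  if (is.null(universe)) universe <- igraph::V(network)$name
  if (!all(igraph::V(network)$name %in% universe))
    stop("network vertices must be contained in the universe")
  term <- intersect(unique(termGenes), universe)
  if (!length(term)) stop("term has no genes in the universe")
  N <- length(universe)
  total <- choose(N, 2)
  m <- length(term)
  M <- choose(m, 2)
  keys <- .edgeKeys(network)
  E <- length(keys)
  if (E == 0) {
    warning("network has no edges; p-value is 1")
    return(data.frame(genes = m, edges = 0L, expected = 0,
                      pValue = 1))
  }
  el <- igraph::as_edgelist(network, names = TRUE)
  k <- sum(el[, 1L] %in% term & el[, 2L] %in% term)
  p <- stats::phyper(k - 1, M, total - M, E, lower.tail = FALSE)
  data.frame(genes = m, edges = k, expected = M * E / total,
             pValue = p)
}

#' Gene-pair enrichment analysis over a gene-set collection
#'
#' Runs [gpeaTest()] for every set of a collection (e.g. read with
#' [readGmt()]), applies size filters on the universe-restricted sets,
#' corrects over the tested terms, and ranks by adjusted p-value.
#'
#' @inheritParams gpeaTest
#' @param collection named list of gene-label vectors; an optional
#'   `description` attribute (named character) supplies term names.
#' @param mtc `"bonferroni"` (default), `"bh"` or `"none"`.
#' @param minGenes,maxGenes size filters on the number of term genes in
#'   the universe (defaults 2 and `Inf`).
#' @return data.frame with columns `term`, `name`, `genes`, `edges`,
#'   `expected`, `pValue`, `adjPValue`, sorted by adjusted then raw
#'   p-value.
#' @export
gpeaAll <- function(network, collection, universe = NULL,
                    mtc = c("bonferroni", "bh", "none"),
                    minGenes = 2L, maxGenes = Inf) {
  mtc <- match.arg(mtc)
  if (is.null(universe)) universe <- igraph::V(network)$name
  desc <- attr(collection, "description")
  sizes <- vapply(collection,
                  function(s) length(intersect(unique(s), universe)),
                  integer(1))
  keep <- which(sizes >= minGenes & sizes <= maxGenes)
  if (!length(keep)) {
    warning("no gene set passes the size filters")
    return(data.frame(term = character(0), name = character(0),
                      genes = integer(0), edges = integer(0),
                      expected = numeric(0), pValue = numeric(0),
                      adjPValue = numeric(0)))
  }
  rows <- lapply(keep, function(i)
    suppressWarnings(gpeaTest(network, collection[[i]], universe)))
  out <- do.call(rbind, rows)
  out <- cbind(term = names(collection)[keep],
               name = if (is.null(desc)) names(collection)[keep]
                      else unname(desc[names(collection)[keep]]),
               out)
  out$adjPValue <- switch(mtc,
    bonferroni = pmin(1, out$pValue * nrow(out)),
    bh = stats::p.adjust(out$pValue, method = "BH"),
    none = out$pValue)
  out <- out[order(out$adjPValue, out$pValue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Components of a network nested in a reference network
#'
#' Builds the concordance graph whose edges are present in *both*
#' networks and returns its connected components (largest first), e.g.
#' the components of an inferred network that are supported by a
#' protein-interaction reference.
#'
#' @param network,reference undirected igraph networks over gene labels.
#' @return list of components, each a list with `genes` (character
#'   vector) and `nEdges` (concordant edge count); singletons (genes
#'   without any concordant edge) are omitted.
#' @export
nestedComponents <- function(network, reference) {
  shared <- intersect(.edgeKeys(network), .edgeKeys(reference))
  if (!length(shared)) return(list())
  gp <- do.call(rbind, strsplit(shared, "\r", fixed = TRUE))
  g <- igraph::graph_from_edgelist(gp, directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  lapply(ord, function(ci) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    list(genes = sort(igraph::V(sub)$name),
         nEdges = as.integer(igraph::ecount(sub)))
  })
}

#' Significance of nested-component sizes by gene-label permutation
#'
#' Tests whether the components of [nestedComponents()] are larger than
#' expected by chance: the network's gene labels are permuted `nPerm`
#' times, the nested components recomputed, and the *maximum* component
#' size per permutation recorded as the (conservative) null statistic. An
#' observed component of size `s` gets
#' `p = (1 + #permutations with max size >= s) / (nPerm + 1)`, Bonferroni
#' corrected over the observed components.
#'
#' @inheritParams nestedComponents
#' @param nPerm number of label permutations, at least 100.
#' @param seed optional integer seed.
#' @param mtc `"bonferroni"` (default) or `"none"`.
#' @return data.frame with one row per observed component: `component`
#'   (rank by size), `genes`, `edges`, `pValue`, `adjPValue`.
#' @export
componentSizePvalues <- function(network, reference, nPerm = 1000L,
                                 seed = NULL,
                                 mtc = c("bonferroni", "none")) {
  mtc <- match.arg(mtc)
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("nPerm must be at least 100")
  obs <- nestedComponents(network, reference)
  if (!length(obs))
    return(data.frame(component = integer(0), genes = integer(0),
                      edges = integer(0), pValue = numeric(0),
                      adjPValue = numeric(0)))
  .setSeed(seed)
  labels <- igraph::V(network)$name
  refKeys <- .edgeKeys(reference)
  el <- igraph::as_edgelist(network, names = TRUE)
  maxSize <- integer(nPerm)
  for (r in seq_len(nPerm)) {
    relab <- stats::setNames(sample(labels), labels)
    keys <- .pairKey(relab[el[, 1L]], relab[el[, 2L]])
    shared <- intersect(keys, refKeys)
    if (!length(shared)) {
      maxSize[r] <- 0L
      next
    }
    gp <- do.call(rbind, strsplit(shared, "\r", fixed = TRUE))
    g <- igraph::graph_from_edgelist(gp, directed = FALSE)
    maxSize[r] <- max(igraph::components(g)$csize)
  }
  sizes <- vapply(obs, function(co) length(co$genes), integer(1))
  p <- vapply(sizes, function(s) (1 + sum(maxSize >= s)) / (nPerm + 1),
              numeric(1))
  padj <- if (mtc == "bonferroni") pmin(1, p * length(p)) else p
  data.frame(component = seq_along(obs), genes = sizes,
             edges = vapply(obs, function(co) co$nEdges, integer(1)),
             pValue = p, adjPValue = padj)
}
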