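# gene-pair enrichment and nested-component significance

# independent oracle: exhaustively place E edges among all pairs of the
# universe and count placements with >= k edges inside the term
enumTail <- function(N, termIdx, E, k) {
  pairs <- combn(N, 2)
  inTerm <- pairs[1, ] %in% termIdx & pairs[2, ] %in% termIdx
  sets <- combn(ncol(pairs), E)
  kk <- colSums(matrix(inTerm[sets], nrow = E))
  mean(kk >= k)
}

test_that("gpea p-value equals exhaustive enumeration on small universes", {
  # worked toy: N=5 (T=10), term of 3 (M=3), E=4, k=2 -> exactly 1/3
  g <- toyGraph(c("a", "b", "a", "c", "a", "d", "d", "e"), letters[1:5])
  res <- gpeaTest(g, c("a", "b", "c"), letters[1:5])
  expect_identical(res$edges, 2L)
  expect_equal(res$pValue, 1 / 3)
  expect_equal(res$expected, 3 * 4 / 10)
  # sweep universes of 4..6 genes, term sizes and edge counts
  for (N in 4:6) {
    uni <- letters[1:N]
    Tpairs <- choose(N, 2)
    for (m in 2:min(4, N)) {
      termIdx <- seq_len(m)
      M <- choose(m, 2)
      for (E in c(1, 3, min(6, Tpairs))) {
        # place E concrete edges at random and compare the returned
        # p-value against the enumeration oracle at the observed k
        set.seed(N * 100 + m * 10 + E)
        pairs <- combn(N, 2)
        pick <- sample(ncol(pairs), E)
        edges <- as.vector(rbind(uni[pairs[1, pick]],
                                 uni[pairs[2, pick]]))
        net <- toyGraph(edges, uni)
        res <- gpeaTest(net, uni[termIdx], uni)
        expect_equal(res$pValue,
                     enumTail(N, termIdx, E, res$edges),
                     tolerance = 1e-12,
                     label = sprintf("N=%d m=%d E=%d", N, m, E))
        # and the whole tail, k by k
        for (k in 0:min(E, M)) {
          p <- phyper(k - 1, M, Tpairs - M, E, lower.tail = FALSE)
          expect_equal(p, enumTail(N, termIdx, E, k), tolerance = 1e-12,
                       label = sprintf("N=%d m=%d E=%d k=%d", N, m, E, k))
        }
      }
    }
  }
})

test_that("gpea handles tails, restriction and degenerate cases", {
  uni <- letters[1:6]
  g <- toyGraph(c("a", "b", "c", "d"), uni)
  # k = 0 -> p = 1
  expect_equal(gpeaTest(g, c("e", "f"), uni)$pValue, 1)
  # term genes outside the universe are dropped before computing m
  r <- gpeaTest(g, c("a", "b", "zzz"), uni)
  expect_identical(r$genes, 2L)
  # empty network: p = 1 with warning
  expect_warning(r0 <- gpeaTest(toyGraph(character(0), uni), c("a", "b"),
                                uni), "no edges")
  expect_equal(r0$pValue, 1)
  # p monotone non-increasing in k at fixed (T, M, E)
  ps <- sapply(0:3, function(k) phyper(k - 1, 3, 12, 6, lower.tail = FALSE))
  expect_true(all(diff(ps) <= 0))
})

test_that("collection-level gpea ranks terms and applies Bonferroni", {
  set.seed(9)
  net <- erdosRenyiNetwork(20, 0.2, 0, seed = 10)
  genes <- igraph::V(net)$name
  coll <- list(t1 = genes[1:5], t2 = genes[6:12], t3 = genes[c(1, 14:16)],
               tiny = genes[1], dup = genes[1:5])
  attr(coll, "description") <- c(t1 = "set one", t2 = "set two",
                                 t3 = "set three", tiny = "singleton",
                                 dup = "copy of one")
  res <- gpeaAll(net, coll)
  # singleton filtered out by minGenes = 2
  expect_false("tiny" %in% res$term)
  expect_identical(nrow(res), 4L)
  # per-term rows agree with direct gpeaTest calls
  for (i in seq_len(nrow(res))) {
    direct <- gpeaTest(net, coll[[res$term[i]]], genes)
    expect_equal(res$pValue[i], direct$pValue)
    expect_identical(res$edges[i], direct$edges)
  }
  expect_equal(res$adjPValue, pmin(1, res$pValue * 4))
  expect_true(!is.unsorted(res$adjPValue))
  # duplicate term: same raw p as its copy
  expect_equal(res$pValue[res$term == "dup"], res$pValue[res$term == "t1"])
  # a single-term collection reduces to gpeaTest with adjusted == raw
  res1 <- gpeaAll(net, coll["t1"])
  expect_equal(res1$adjPValue, res1$pValue)
  # expected edges over a disjoint partition never exceed the edge total
  part <- list(p1 = genes[1:7], p2 = genes[8:14], p3 = genes[15:20])
  resP <- gpeaAll(net, part)
  expect_lte(sum(resP$expected), igraph::ecount(net))
})

test_that("nested components are the components of the concordance graph", {
  uni <- sprintf("g%d", 1:8)
  a <- toyGraph(c("g1", "g2", "g2", "g3", "g4", "g5", "g6", "g7",
                  "g7", "g8"), uni)
  b <- toyGraph(c("g1", "g2", "g2", "g3", "g6", "g7", "g7", "g8",
                  "g1", "g5"), uni)
  comps <- nestedComponents(a, b)
  expect_length(comps, 2)
  expect_identical(comps[[1]]$genes, c("g1", "g2", "g3"))
  expect_identical(comps[[1]]$nEdges, 2L)
  expect_identical(comps[[2]]$genes, c("g6", "g7", "g8"))
  # network == reference -> the network's own components
  self <- nestedComponents(a, a)
  expect_equal(sum(sapply(self, function(co) co$nEdges)),
               igraph::ecount(a))
  # disjoint edge sets -> nothing
  expect_length(nestedComponents(toyGraph(c("g1", "g2"), uni),
                                 toyGraph(c("g3", "g4"), uni)), 0)
})

test_that("component-size significance uses the max-size permutation null", {
  set.seed(4)
  uni <- sprintf("g%02d", 1:20)
  # a large shared path should be significant; build identical chains
  chain <- as.vector(rbind(uni[1:9], uni[2:10]))
  net <- toyGraph(chain, uni)
  ref <- toyGraph(chain, uni)
  res <- componentSizePvalues(net, ref, nPerm = 200, seed = 5)
  expect_identical(nrow(res), 1L)
  expect_identical(res$genes, 10L)
  expect_lte(res$pValue, 0.05)
  expect_gte(res$adjPValue, res$pValue)
  # seeded determinism
  res2 <- componentSizePvalues(net, ref, nPerm = 200, seed = 5)
  expect_identical(res, res2)
  # extreme tail: observed larger than every permuted maximum
  if (all(res$pValue == 1 / 201)) succeed()
})
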