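two_clique_collection <- function() {
  # two disjoint unit 4-cliques: each clique holds exactly half the weight
  g <- mat_graph(8, c(combn(letters[1:4], 2, simplify = FALSE),
                      combn(letters[5:8], 2, simplify = FALSE)),
                 nodes = letters[1:8], name = "cliques")
  rescaleCollection(list(g))
}

test_that("cluster modularity matches its closed form on fixtures", {
  gc <- two_clique_collection()
  g <- graphs(gc)[[1]]
  expect_equal(clusterModularity(g, nodes(g)), 0)            # whole graph
  expect_equal(clusterModularity(g, letters[1:4]), 0.25)     # 0.5 - 0.25
  expect_lte(clusterModularity(g, "a"), 0)                   # no internal edges

  # min-modularity: identical graphs reduce to the single-graph score and
  # the minimum never exceeds any per-graph score
  g2 <- weightedGraph(edgeWeights(g), "copy")
  gc2 <- rescaleCollection(list(g, g2))
  expect_equal(minModularity(gc2, letters[1:4]),
               clusterModularity(g, letters[1:4]))
  gr <- random_graph(8, seed = 31, name = "noise")
  rownames(gr@weights) <- colnames(gr@weights) <- letters[1:8]
  gc3 <- rescaleCollection(list(g, gr))
  mm <- minModularity(gc3, letters[1:4])
  for (gg in graphs(gc3))
    expect_lte(mm, clusterModularity(gg, letters[1:4]) + 1e-12)
})

test_that("a cluster strong in one graph but random in the other scores ~0", {
  g <- two_clique_collection()
  strong <- graphs(g)[[1]]                       # Q = 0.25 for a clique
  set.seed(40)
  perm <- sample(letters[1:8])
  Wr <- edgeWeights(strong)[perm, perm]
  dimnames(Wr) <- dimnames(edgeWeights(strong))  # same structure, shuffled
  gc <- rescaleCollection(list(strong, weightedGraph(Wr, "shuffled")))
  mm <- minModularity(gc, letters[1:4])
  expect_lt(mm, 0.1)
  expect_equal(clusterModularity(strong, letters[1:4]), 0.25)
})

test_that("tree parsing keeps or splits by the min-modularity DP", {
  gc <- two_clique_collection()
  root <- list(set = letters[1:8], cut = NULL,
               left = list(set = letters[1:4], cut = NULL, left = NULL, right = NULL),
               right = list(set = letters[5:8], cut = NULL, left = NULL, right = NULL))
  tree <- new("ClusteringTree", root = root, nodeSet = letters[1:8],
              alphas = 0.5, mode = "basic")
  p <- parseTree(tree, gc)
  expect_equal(length(clusters(p)), 2)           # split: 2 x 0.25 > 0
  expect_setequal(clusters(p)[[1]], letters[1:4])
  expect_equal(unname(minModularityScores(p)), c(0.25, 0.25))

  leaf <- new("ClusteringTree",
              root = list(set = letters[1:8], cut = NULL, left = NULL, right = NULL),
              nodeSet = letters[1:8], alphas = 0.5, mode = "basic")
  pl <- parseTree(leaf, gc)
  expect_equal(clusters(pl), list(letters[1:8]))  # single-leaf tree

  # any parse scores at least the root kept whole
  expect_gte(sum(minModularityScores(p)), minModularity(gc, letters[1:8]))
})

test_that("the frontier DP equals exhaustive frontier search on random trees", {
  for (s in 1:25) {
    n <- sample(8:14, 1)
    g1 <- random_graph(n, seed = 800 + s, name = "g1")
    g2 <- random_graph(n, seed = 900 + s, name = "g2")
    gc <- rescaleCollection(list(g1, g2))
    root <- random_tree(nodes(gc), seed = s)
    tree <- new("ClusteringTree", root = root, nodeSet = nodes(gc),
                alphas = c(0.5, 0.5), mode = "basic")
    p <- parseTree(tree, gc)
    oracle <- oracle_best_frontier(root, function(set) minModularity(gc, set))
    expect_equal(sum(minModularityScores(p)), oracle, tolerance = 1e-10)
  }
})

test_that("partition ranking is stable under graph input order", {
  sim <- simulateGraphs(simConfig(nNodes = 32, nClusters = 2, kTotal = 8,
                                  kOut = 2), seed = 17)
  gc <- sim$collection
  gcRev <- rescaleCollection(rev(graphs(gc)))
  p1 <- scorePartition(clusters(sim$truth), gc)
  p2 <- scorePartition(clusters(sim$truth), gcRev)
  expect_equal(clusters(p1), clusters(p2))
  expect_equal(minModularityScores(p1), minModularityScores(p2))
})

test_that("modularity conservation holds per graph for any partition", {
  sim <- simulateGraphs(simConfig(nNodes = 32, nClusters = 4, kTotal = 8,
                                  kOut = 4), seed = 23)
  gc <- sim$collection
  cl <- clusters(sim$truth)
  for (g in graphs(gc)) {
    withinFrac <- sum(vapply(cl, function(C)
      sum(edgeWeights(g)[C, C]) / 2, 0)) / totalWeight(g)
    crossFrac <- interclusterCost(rescaleCollection(list(g)), cl)
    expect_equal(withinFrac + crossFrac, 1, tolerance = 1e-9)
  }
})

test_that("planted clusters are significantly modular, p-values in (0,1]", {
  sim <- simulateGraphs(simConfig(nNodes = 48, nClusters = 3, kTotal = 10,
                                  kOut = 2), seed = 3)
  gc <- sim$collection
  pv <- modularitySignificance(gc, clusters(sim$truth)[[1]], nNull = 199,
                               seed = 5)
  expect_true(all(pv > 0 & pv <= 1))
  expect_true(all(pv <= 0.02))
  # a random node set is not significant
  set.seed(6)
  rnd <- sample(nodes(gc), 16)
  pr <- modularitySignificance(gc, rnd, nNull = 199, seed = 7)
  expect_true(all(pr > 0 & pr <= 1))
})
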