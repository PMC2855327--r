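two_graph_collection <- function(seed = 1, n = 12) {
  g1 <- random_graph(n, seed = seed, name = "g1")
  g2 <- random_graph(n, seed = seed + 1000, name = "g2")
  rescaleCollection(list(g1, g2))
}

test_that("sum, min and mixture graphs follow their definitions", {
  gc <- two_graph_collection(seed = 3)
  W1 <- edgeWeights(graphs(gc)[[1]])
  W2 <- edgeWeights(graphs(gc)[[2]])

  expect_equal(edgeWeights(sumGraph(gc)), W1 + W2)
  expect_equal(totalWeight(sumGraph(gc)), 2 * commonTotal(gc))
  expect_equal(edgeWeights(minGraph(gc)), pmin(W1, W2))
  expect_true(all(edgeWeights(minGraph(gc)) <= W1 + 1e-12))

  gc1 <- rescaleCollection(list(graphs(gc)[[1]]))
  expect_equal(edgeWeights(sumGraph(gc1)), W1)   # k = 1 identity
  expect_equal(edgeWeights(minGraph(gc1)), W1)

  # mixtures: s = 1 is the sum graph, large s converges to the base graph
  expect_equal(edgeWeights(mixtureGraph(gc, 1, 1)), W1 + W2)
  expect_equal(edgeWeights(mixtureGraph(gc, 1, 2)), W1 + 0.5 * W2)
  dev <- max(abs(edgeWeights(mixtureGraph(gc, 2, 1e9)) - W2))
  expect_lt(dev, 1e-6 * commonTotal(gc))
  expect_error(mixtureGraph(gc, 1, 0.5), ">= 1")
})

test_that("min graph of edge-disjoint graphs is empty and flagged", {
  ga <- mat_graph(4, list(c("a", "b")), nodes = letters[1:4], name = "ga")
  gb <- mat_graph(4, list(c("c", "d")), nodes = letters[1:4], name = "gb")
  gc <- rescaleCollection(list(ga, gb))
  expect_warning(mg <- minGraph(gc), "share no edges")
  expect_true(all(edgeWeights(mg) == 0))
})

test_that("sparse-enough is a strict threshold comparison", {
  g <- barbell_graph()
  cut <- new("Cut", side = c("a", "b", "c"), otherSide = c("d", "e", "f"),
             conductances = numeric(), source = "barbell", scale = NA_real_)
  expect_true(sparseEnough(g, cut, alpha = 0.2))       # 1/7 < 0.2
  expect_false(sparseEnough(g, cut, alpha = 0.1))      # 1/7 > 0.1
  expect_false(sparseEnough(g, cut, alpha = 1 / 7))    # boundary is strict
  gd <- two_triangles_graph()
  cut0 <- new("Cut", side = c("a", "b", "c"), otherSide = c("d", "e", "f"),
              conductances = numeric(), source = "x", scale = NA_real_)
  expect_true(sparseEnough(gd, cut0, alpha = 0.01))    # conductance 0
})

test_that("best-cut selection counts graphs first, then crossing cost", {
  # two copies of a barbell with a light (0.2) bridge; cuts annotated with
  # their per-input-graph conductances, selection verified against the rule
  base <- mat_graph(6, list(c("a", "b"), c("b", "c"), c("a", "c"),
                            c("d", "e"), c("e", "f"), c("d", "f"),
                            c("c", "d", 0.2)), name = "g1")
  g2 <- weightedGraph(edgeWeights(base), "g2")
  gc <- rescaleCollection(list(base, g2), alphas = c(0.3, 0.3))
  C <- nodes(gc)
  mk <- function(side, src) {
    phi <- vapply(graphs(gc), cutConductance, 0, S = side)
    new("Cut", side = side, otherSide = setdiff(C, side),
        conductances = stats::setNames(phi, c("g1", "g2")),
        source = src, scale = NA_real_)
  }
  X <- mk(c("a", "b", "c"), "g1")       # bridge cut: sparse in both graphs
  Y <- mk(c("a", "b"), "g1")            # expensive cut: sparse in neither
  expect_equal(sum(X@conductances < 0.3), 2)
  expect_equal(sum(Y@conductances < 0.3), 0)
  expect_equal(bestCut(list(Y, X), gc, C)@side, X@side)  # count beats order
  expect_equal(bestCut(list(X), gc, C)@side, X@side)     # single candidate
  expect_null(bestCut(list(), gc, C))

  # equal sparse-enough counts: the cheaper aggregated crossing cost wins
  Q <- mk(c("a", "b", "c", "d"), "g2")  # detaches d: crossing 2.2 vs 0.2
  Q@conductances[] <- X@conductances    # force an equal count
  pick <- bestCut(list(Q, X), gc, C)
  expect_setequal(pick@side, X@side)
})

test_that("the tree on two planted cliques recovers them as leaves", {
  g1 <- clique_pair_graph(12, "c1")
  g2 <- clique_pair_graph(12, "c2")
  gc <- rescaleCollection(list(g1, g2), alphas = c(0.1, 0.1))
  # phi(bridge) = 1/133 < 0.1 < 6/11 <= phi of any within-clique cut
  tr <- jointClusterTree(gc, mode = "scaling")
  lv <- treeLeaves(tr)
  expect_equal(length(lv), 2)
  expect_setequal(lv[[which(vapply(lv, function(x) "n01" %in% x, TRUE))]],
                  sprintf("n%02d", 1:12))
  trb <- jointClusterTree(gc, mode = "basic")
  expect_equal(length(treeLeaves(trb)), 2)
})

test_that("leaves partition V and scales never decrease along paths", {
  check_scales <- function(node, smin) {
    if (is.null(node$left)) return(invisible(TRUE))
    s <- node$cut@scale
    if (!is.na(s) && !is.na(smin)) expect_gte(s, smin)
    nxt <- if (is.na(s)) smin else s
    check_scales(node$left, nxt)
    check_scales(node$right, nxt)
  }
  for (s in 1:4) {
    sim <- simulateGraphs(simConfig(nNodes = 48, nClusters = 3, kTotal = 10,
                                    kOut = 2), seed = 600 + s)
    gc <- sim$collection
    alphas(gc) <- unname(learnAlphas(gc))
    for (mode in c("scaling", "basic")) {
      tr <- jointClusterTree(gc, mode = mode)
      lv <- treeLeaves(tr)
      expect_setequal(unlist(lv), nodes(gc))
      expect_equal(length(unlist(lv)), length(nodes(gc)))  # no duplication
      if (mode == "scaling") check_scales(tr@root, 1)
    }
  }
})

test_that("leaf node sets admit no sparse-enough cut in any input graph", {
  sim <- simulateGraphs(simConfig(nNodes = 48, nClusters = 3, kTotal = 10,
                                  kOut = 2), seed = 9)
  gc <- sim$collection
  alphas(gc) <- unname(learnAlphas(gc))
  tr <- jointClusterTree(gc, mode = "basic")
  for (leaf in treeLeaves(tr)) {
    if (length(leaf) < 2) next
    for (i in seq_along(graphs(gc))) {
      g <- graphs(gc)[[i]]
      W <- edgeWeights(g)[leaf, leaf]
      if (all(W == 0)) next
      sw <- approxSparsestCut(g, C = leaf)
      cut <- improveCut(g, sw@cut, C = leaf)
      expect_gte(cutConductance(g, cut@side, leaf), alphas(gc)[i])
    }
  }
})

test_that("k = 1 recursion and degenerate multi-graph cases coincide", {
  for (s in 1:10) {
    g <- random_graph(12, seed = 700 + s)
    gc1 <- rescaleCollection(list(g))
    a <- 0.6  # permissive fixed threshold: random graphs are expander-like
    alphas(gc1) <- a
    basic <- jointClusterTree(gc1, mode = "basic")
    scaled <- jointClusterTree(gc1, mode = "scaling")
    # k = 1: every mixture equals the graph itself, so both modes agree
    expect_equal(treeLeaves(scaled), treeLeaves(basic))

    # two identical copies: mixtures are all proportional to the graph
    g2 <- weightedGraph(edgeWeights(g), "copy")
    gc2 <- rescaleCollection(list(g, g2))
    alphas(gc2) <- c(a, a)
    expect_equal(treeLeaves(jointClusterTree(gc2, mode = "scaling")),
                 treeLeaves(basic))
    expect_equal(treeLeaves(jointClusterTree(gc2, mode = "basic")),
                 treeLeaves(basic))
  }
})

test_that("threshold learning lands between separation and cohesion", {
  g <- clique_pair_graph(6)   # 12 nodes: phi(bridge)=1/61, within >= 0.5
  gc <- rescaleCollection(list(g))
  a <- learnAlphas(gc)
  expect_gte(unname(a), 0.01)
  expect_lte(unname(a), 0.5)
  expect_gt(unname(a), cutConductance(g, sprintf("n%02d", 1:6)) - 1e-12)
  expect_lt(unname(a), clusterConductance(g, sprintf("n%02d", 1:6),
                                          mode = "spectral-bound"))

  # identical graphs learn identical thresholds (per-graph procedure)
  g2 <- weightedGraph(edgeWeights(g), "copy")
  a2 <- learnAlphas(rescaleCollection(list(g, g2)))
  expect_equal(unname(a2[1]), unname(a2[2]))

  # a clique admits no cut below the permissive threshold
  k4 <- mat_graph(4, combn(letters[1:4], 2, simplify = FALSE))
  expect_error(learnAlphas(rescaleCollection(list(k4))), "no cut below")

  expect_error(jointClusterTree(rescaleCollection(list(g))), "learnAlphas")
})
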