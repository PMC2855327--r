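# Planted-partition multi-graph simulator, pair-counting Jaccard evaluation,
# and the baseline methods (single-graph / single-tree clustering and
# coassociation consensus).

#' Configure the planted-partition simulator
#'
#' @param nNodes number of nodes (default 128).
#' @param nClusters number of equal-sized planted clusters (default 4).
#' @param kTotal expected total degree per node (default 16).
#' @param kOut expected inter-cluster degree per node; `kOut / kTotal` is the
#'   false positive rate of a simulated graph.  A vector of length `nGraphs`
#'   gives each graph its own noise level (asymmetric design).
#' @param nGraphs number of graphs sharing the planted clustering (default 2).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nNodes = 128L, nClusters = 4L, kTotal = 16, kOut = 4,
                      nGraphs = 2L) {
  new("SimConfig", nNodes = as.numeric(nNodes), nClusters = as.numeric(nClusters),
      kTotal = as.numeric(kTotal), kOut = as.numeric(kOut),
      nGraphs = as.numeric(nGraphs))
}

#' Simulate planted-partition multi-graphs
#'
#' Generates `nGraphs` independent unit-weight random graphs carrying the
#' same planted clustering of equal-sized clusters.  Each within-cluster pair
#' is an edge with probability `p_in = (kTotal - kOut) / (clusterSize - 1)`
#' and each between-cluster pair with `p_out = kOut / (nNodes - clusterSize)`,
#' so expectations (not exact degrees) match the configured averages.
#'
#' @param cfg a [SimConfig-class].
#' @param seed RNG seed.
#' @return List with elements `collection` (a rescaled
#'   [GraphCollection-class]) and `truth` (the planted [Partition-class],
#'   scored against the collection).
#' @export
simulateGraphs <- function(cfg, seed = 1L) {
  validObject(cfg)
  set.seed(seed)
  n <- as.integer(cfg@nNodes)
  m <- as.integer(cfg@nClusters)
  csize <- n %/% m
  genes <- sprintf("g%04d", seq_len(n))
  memb <- rep(seq_len(m), each = csize)
  kOut <- rep(cfg@kOut, length.out = cfg@nGraphs)
  same <- outer(memb, memb, "==")
  ut <- upper.tri(same)
  gs <- vector("list", cfg@nGraphs)
  for (gi in seq_len(cfg@nGraphs)) {
    pin <- (cfg@kTotal - kOut[gi]) / (csize - 1)
    pout <- kOut[gi] / (n - csize)
    p <- ifelse(same[ut], pin, pout)
    A <- matrix(0, n, n, dimnames = list(genes, genes))
    A[ut] <- as.numeric(runif(sum(ut)) < p)
    gs[[gi]] <- weightedGraph(A + t(A), sprintf("sim%d", gi))
  }
  truthClusters <- split(genes, memb)
  names(truthClusters) <- NULL
  coll <- rescaleCollection(gs)
  list(collection = coll, truth = scorePartition(truthClusters, coll))
}

#' Empirical false positive rate of a simulated graph
#'
#' The fraction of a graph's total edge weight that crosses the planted
#' clusters; for the planted-partition simulator its expectation is
#' `kOut / kTotal`.  Scale-invariant, so rescaling does not affect it.
#'
#' @param g a [WeightedGraph-class].
#' @param truth the planted [Partition-class] (or list of node sets).
#' @return Fraction in [0, 1].
#' @export
falsePositiveRate <- function(g, truth) {
  cl <- if (is(truth, "Partition")) truth@clusters else truth
  nm <- nodes(g)
  lab <- integer(length(nm)); names(lab) <- nm
  for (i in seq_along(cl)) lab[cl[[i]]] <- i
  same <- outer(lab, lab, "==")
  sum(g@weights[!same]) / sum(g@weights)
}

#' Pair-counting Jaccard index between two partitions
#'
#' `n11 / (n11 + n10 + n01)` over unordered node pairs, where `n11` counts
#' pairs co-clustered in both partitions and `n10`/`n01` pairs co-clustered
#' in only one.  Ranges from 0 to 1; equals 1 exactly for identical
#' partitions (up to label permutation) and 0 when no pair is co-clustered in
#' either partition (convention).
#'
#' @param p,q [Partition-class] objects (or lists of node sets) over the same
#'   node set.
#' @return Jaccard index in [0, 1].
#' @export
jaccardIndex <- function(p, q) {
  cp <- if (is(p, "Partition")) p@clusters else p
  cq <- if (is(q, "Partition")) q@clusters else q
  np <- unlist(cp, use.names = FALSE)
  nq <- unlist(cq, use.names = FALSE)
  if (!setequal(np, nq)) stop("partitions cover different node sets", call. = FALSE)
  lp <- rep(seq_along(cp), lengths(cp))[order(np)]
  lq <- rep(seq_along(cq), lengths(cq))[order(nq)]
  N <- table(lp, lq)
  n11 <- sum(choose(N, 2))
  n1x <- sum(choose(rowSums(N), 2))
  nx1 <- sum(choose(colSums(N), 2))
  den <- n1x + nx1 - n11  # n11 + n10 + n01
  if (den == 0) return(0)
  n11 / den
}

#' Single-graph (single-tree) baseline clustering
#'
#' Grows the clustering tree of one graph alone with the basic single-graph
#' recursion and parses it with the min-modularity computed over
#' `gcScoring`.  With `gcScoring` containing only `g` itself this is the
#' plain single-graph method; with the full collection it is the single-tree
#' baseline (one reference graph's tree, all graphs' scores).
#'
#' @param g a [WeightedGraph-class].
#' @param gcScoring a [GraphCollection-class] over the same node set used for
#'   min-modularity parsing.
#' @param seed kept for interface stability.
#' @param alpha conductance threshold for `g`; learnt from `g` when `NULL`.
#' @param minSize recursion floor.
#' @return A [Partition-class].
#' @export
singleGraphCluster <- function(g, gcScoring, seed = 0L, alpha = NULL,
                               minSize = 2L) {
  gcSelf <- rescaleCollection(list(g))
  if (is.null(alpha)) alpha <- unname(learnAlphas(gcSelf, seed = seed))
  alphas(gcSelf) <- alpha
  tree <- jointClusterTree(gcSelf, mode = "basic", seed = seed,
                           minSize = minSize)
  parseTree(tree, gcScoring)
}

#' Coassociation consensus baseline
#'
#' Clusters each graph separately with the single-graph method, builds the
#' coassociation graph whose edge weight counts in how many per-graph
#' clusterings a node pair is co-clustered, clusters that graph with the same
#' single-graph method, and parses with min-modularity over the original
#' collection.
#'
#' @param gc a [GraphCollection-class] with k >= 2 graphs.
#' @param seed kept for interface stability.
#' @param alphasPerGraph optional per-graph thresholds for the separate
#'   clusterings (learnt when `NULL`).
#' @param minSize recursion floor.
#' @return A [Partition-class].
#' @export
coassociationCluster <- function(gc, seed = 0L, alphasPerGraph = NULL,
                                 minSize = 2L) {
  if (length(gc@graphs) < 2L)
    stop("coassociation needs at least two graphs", call. = FALSE)
  nm <- nodes(gc)
  co <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(gc@graphs)) {
    g <- gc@graphs[[i]]
    p <- singleGraphCluster(g, rescaleCollection(list(g)), seed = seed,
                            alpha = alphasPerGraph[i], minSize = minSize)
    lab <- integer(length(nm)); names(lab) <- nm
    for (j in seq_along(p@clusters)) lab[p@clusters[[j]]] <- j
    co <- co + outer(lab, lab, "==")
  }
  diag(co) <- 0
  cog <- weightedGraph(co, "coassociation")
  singleGraphCluster(cog, gc, seed = seed, minSize = minSize)
}

#' Run the planted-recovery benchmark
#'
#' For every configuration and method, simulates `instances` independent
#' planted-partition multi-graphs, runs the method, and records the
#' pair-counting Jaccard index against the planted truth.
#'
#' Methods: `"joint"` (scaling-mode joint tree, learnt thresholds),
#' `"basic"` (basic-mode joint tree), `"coassoc"` (coassociation consensus),
#' and `"tree<i>"` (single tree of graph i parsed against all graphs).
#'
#' @param configs list of [SimConfig-class] objects (a single config is
#'   accepted).
#' @param methods character vector of method names.
#' @param instances random instances per configuration (>= 2).
#' @param seed base RNG seed; instance seeds are derived deterministically.
#' @return List with `summary` (mean and sd of Jaccard per config x method)
#'   and `raw` (per-instance results) data frames.
#' @export
runBenchmark <- function(configs, methods = c("joint", "coassoc", "tree1", "tree2"),
                         instances = 20L, seed = 1L) {
  if (is(configs, "SimConfig")) configs <- list(configs)
  if (instances < 2L) stop("use at least 2 instances", call. = FALSE)
  raw <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (t in seq_len(instances)) {
      sim <- simulateGraphs(cfg, seed = seed + 7919L * ci + t)
      gc <- sim$collection
      la <- learnAlphas(gc, seed = seed)
      for (meth in methods) {
        p <- switch(
          meth,
          joint = {
            gcj <- gc; alphas(gcj) <- unname(la)
            parseTree(jointClusterTree(gcj, mode = "scaling", seed = seed), gcj)
          },
          basic = {
            gcj <- gc; alphas(gcj) <- unname(la)
            parseTree(jointClusterTree(gcj, mode = "basic", seed = seed), gcj)
          },
          coassoc = coassociationCluster(gc, seed = seed,
                                         alphasPerGraph = unname(la)),
          {
            gi <- as.integer(sub("^tree", "", meth))
            if (is.na(gi) || gi < 1L || gi > length(gc@graphs))
              stop("unknown method '", meth, "'", call. = FALSE)
            singleGraphCluster(gc@graphs[[gi]], gc, seed = seed,
                               alpha = unname(la)[gi])
          })
        raw[[length(raw) + 1L]] <- data.frame(
          config = ci, kOut = paste(cfg@kOut, collapse = "/"),
          method = meth, instance = t,
          jaccard = jaccardIndex(p, sim$truth),
          nClusters = length(p@clusters))
      }
    }
  }
  raw <- do.call(rbind, raw)
  agg <- aggregate(jaccard ~ config + kOut + method, data = raw,
                   FUN = function(x) c(mean = mean(x), sd = sd(x)))
  summary <- data.frame(agg[c("config", "kOut", "method")],
                        meanJaccard = agg$jaccard[, "mean"],
                        sdJaccard = agg$jaccard[, "sd"],
                        n = instances)
  list(summary = summary[order(summary$config, summary$method), ], raw = raw)
}
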