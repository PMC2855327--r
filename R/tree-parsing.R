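# Modularity scoring of tree nodes and the frontier dynamic program that
# turns a clustering tree into final clusters.

# per-graph modularity pieces, precomputed once per collection
.modEnv <- function(gc) {
  Ws <- lapply(gc@graphs, slot, "weights")
  list(Ws = Ws,
       deg = lapply(Ws, rowSums),
       wT = vapply(Ws, function(W) sum(W) / 2, 0))
}

.modQ <- function(me, j, idx) {
  W <- me$Ws[[j]]
  within <- sum(W[idx, idx]) / 2
  aC <- sum(me$deg[[j]][idx])
  within / me$wT[j] - (aC / (2 * me$wT[j]))^2
}

.minQ <- function(me, idx) {
  min(vapply(seq_along(me$Ws), function(j) .modQ(me, j, idx), 0))
}

#' Newman modularity of one cluster in one graph
#'
#' `Q(C) = w(C,C)/w(E) - (a(C) / (2 w(E)))^2`: the fraction of edge weight
#' inside the cluster minus the fraction expected under degree-preserving
#' randomisation (the closed-form expectation of a degree-preserved shuffle;
#' `a(C)` is the incident weight of `C`).
#'
#' @param g a [WeightedGraph-class].
#' @param C node set.
#' @return Modularity score (can be negative; 0 for the whole node set).
#' @export
clusterModularity <- function(g, C) {
  idx <- .idx(g, C)
  W <- g@weights
  wT <- sum(W) / 2
  sum(W[idx, idx]) / 2 / wT - (sum(W[idx, ]) / (2 * wT))^2
}

#' Minimum modularity of a cluster across a collection
#'
#' Scores a cluster in every graph of the collection and aggregates by the
#' minimum, so a cluster only scores well when it holds up in all networks.
#'
#' @param gc a [GraphCollection-class].
#' @param C node set.
#' @return min over graphs of [clusterModularity()].
#' @export
minModularity <- function(gc, C) {
  min(vapply(gc@graphs, clusterModularity, 0, C = C))
}

#' Score a fixed list of clusters against a collection
#'
#' Builds a [Partition-class] with per-graph and min-modularity scores,
#' ordered by decreasing min-modularity (rank 1 = best).
#'
#' @param clusters list of disjoint character vectors covering the node set
#'   (or a [Partition-class] to re-score).
#' @param gc a [GraphCollection-class].
#' @return A [Partition-class].
#' @export
scorePartition <- function(clusters, gc) {
  if (is(clusters, "Partition")) clusters <- clusters@clusters
  me <- .modEnv(gc)
  nmAll <- nodes(gc)
  Q <- t(vapply(clusters, function(C) {
    idx <- match(C, nmAll)
    vapply(seq_along(me$Ws), function(j) .modQ(me, j, idx), 0)
  }, numeric(length(gc@graphs))))
  Q <- matrix(Q, ncol = length(gc@graphs),
              dimnames = list(NULL, vapply(gc@graphs, graphName, "")))
  mm <- apply(Q, 1L, min)
  # rank by decreasing min-modularity; ties by size then leading gene
  o <- order(-mm, -lengths(clusters),
             vapply(clusters, function(C) sort(C)[1L], ""))
  new("Partition", clusters = clusters[o],
      perGraphModularity = Q[o, , drop = FALSE], minModularity = mm[o])
}

#' Parse a clustering tree into final clusters
#'
#' Bottom-up dynamic program over the tree: the score of a node is the larger
#' of (a) the min-modularity of its node set kept whole, and (b) the sum of
#' the optimal scores of its two children.  Ties keep the single coarser
#' cluster.  The optimal frontier maximises the clustering score (the sum of
#' constituent min-modularity scores) over all frontiers of the tree, and is
#' returned as a [Partition-class] ranked by min-modularity.
#'
#' @param tree a [ClusteringTree-class].
#' @param gc the [GraphCollection-class] the tree was grown from (or any
#'   collection over the same node set to score against).
#' @return A [Partition-class].
#' @export
parseTree <- function(tree, gc) {
  if (!setequal(tree@nodeSet, nodes(gc)))
    stop("tree and collection disagree on the node set", call. = FALSE)
  me <- .modEnv(gc)
  nmAll <- nodes(gc)
  rec <- function(node) {
    keep <- .minQ(me, match(node$set, nmAll))
    if (is.null(node$left))
      return(list(score = keep, clusters = list(node$set)))
    l <- rec(node$left)
    r <- rec(node$right)
    if (keep >= l$score + r$score)  # tie -> coarser cluster
      list(score = keep, clusters = list(node$set))
    else
      list(score = l$score + r$score, clusters = c(l$clusters, r$clusters))
  }
  res <- rec(tree@root)
  scorePartition(res$clusters, gc)
}

#' Empirical modularity significance of a cluster
#'
#' For each graph, compares the cluster's modularity with the modularity of
#' `nNull` uniformly drawn node sets of the same size; the p-value is the
#' add-one-smoothed fraction of null sets scoring at least as high,
#' `p = (r + 1) / (nNull + 1)`, always in (0, 1].
#'
#' @param gc a [GraphCollection-class].
#' @param C node set.
#' @param nNull number of null draws (>= 100).
#' @param seed RNG seed.
#' @return Named numeric vector of per-graph p-values.
#' @export
modularitySignificance <- function(gc, C, nNull = 999L, seed = 1L) {
  if (nNull < 100L) stop("use at least 100 null draws", call. = FALSE)
  nmAll <- nodes(gc)
  if (length(C) > length(nmAll)) stop("cluster larger than the node set", call. = FALSE)
  me <- .modEnv(gc)
  idx <- match(C, nmAll)
  obs <- vapply(seq_along(me$Ws), function(j) .modQ(me, j, idx), 0)
  set.seed(seed)
  draws <- matrix(replicate(nNull, sample.int(length(nmAll), length(C))),
                  nrow = length(C))
  r <- numeric(length(me$Ws))
  for (b in seq_len(nNull)) {
    di <- draws[, b]
    for (j in seq_along(me$Ws))
      if (.modQ(me, j, di) >= obs[j] - 1e-12) r[j] <- r[j] + 1
  }
  stats::setNames((r + 1) / (nNull + 1), vapply(gc@graphs, graphName, ""))
}
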