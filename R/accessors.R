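#' Construct a weighted network from a symmetric weight matrix
#'
#' @param weights symmetric numeric matrix with non-negative entries, zero
#'   diagonal, and gene identifiers as dimnames (rownames are used if
#'   colnames are missing).
#' @param name label for the network.
#' @return A [WeightedGraph-class].
#' @examples
#' W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' W["a", "b"] <- W["b", "a"] <- 1
#' g <- weightedGraph(W, "toy")
#' totalWeight(g)
#' @export
weightedGraph <- function(weights, name = "graph") {
  weights <- as.matrix(weights)
  if (is.null(colnames(weights))) colnames(weights) <- rownames(weights)
  storage.mode(weights) <- "double"
  weights <- (weights + t(weights)) / 2  # remove numeric asymmetry
  new("WeightedGraph", weights = weights, name = as.character(name))
}

#' Node identifiers of an object
#'
#' @param x a [WeightedGraph-class], [GraphCollection-class],
#'   [ClusteringTree-class] or [Partition-class].
#' @return Character vector of gene identifiers.
#' @export
#' @name nodes
#' @aliases nodes,WeightedGraph-method
setMethod("nodes", "WeightedGraph", function(x) rownames(x@weights))

#' @rdname nodes
#' @export
setMethod("nodes", "GraphCollection", function(x) rownames(x@graphs[[1L]]@weights))

#' @rdname nodes
#' @export
setMethod("nodes", "ClusteringTree", function(x) x@nodeSet)

#' @rdname nodes
#' @export
setMethod("nodes", "Partition",
          function(x) unlist(x@clusters, use.names = FALSE))

#' Accessors for jointclust classes
#'
#' `graphName`, `edgeWeights` and `totalWeight` read a single network;
#' `graphs`, `commonTotal`, `alphas` read a collection; `className` and
#' `geneSets` read a gene-set collection; `clusters`, `modularityMatrix` and
#' `minModularityScores` read a partition; `treeLeaves` returns the leaf node
#' sets of a clustering tree (which always partition the gene universe).
#'
#' @param x the object.
#' @param value replacement value (for `alphas<-`: per-graph thresholds in
#'   (0,1)).
#' @return The slot contents; `treeLeaves` a list of character vectors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("graphName", "WeightedGraph", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("edgeWeights", "WeightedGraph", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("totalWeight", "WeightedGraph", function(x) sum(x@weights) / 2)

#' @rdname accessors
#' @export
setMethod("graphs", "GraphCollection", function(x) x@graphs)

#' @rdname accessors
#' @export
setMethod("commonTotal", "GraphCollection", function(x) x@commonTotal)

#' @rdname accessors
#' @export
setMethod("alphas", "GraphCollection", function(x) x@alphas)

#' @rdname accessors
#' @export
setReplaceMethod("alphas", "GraphCollection", function(x, value) {
  x@alphas <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("alphas", "ClusteringTree", function(x) x@alphas)

#' @rdname accessors
#' @export
setMethod("className", "GeneSetCollection", function(x) x@className)

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("clusters", "Partition", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("modularityMatrix", "Partition", function(x) x@perGraphModularity)

#' @rdname accessors
#' @export
setMethod("minModularityScores", "Partition", function(x) x@minModularity)

#' @rdname accessors
#' @export
setMethod("treeLeaves", "ClusteringTree", function(x) .treeLeafSets(x@root))

#' @rdname accessors
#' @export
setMethod("length", "GraphCollection", function(x) length(x@graphs))

#' @rdname accessors
#' @export
setMethod("length", "Partition", function(x) length(x@clusters))

#' @rdname accessors
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "WeightedGraph", function(object) {
  W <- object@weights
  cat(sprintf("WeightedGraph '%s': %d nodes, %d edges, total weight %.4g\n",
              object@name, nrow(W), sum(W[upper.tri(W)] > 0), sum(W) / 2))
})

setMethod("show", "GraphCollection", function(object) {
  cat(sprintf("GraphCollection: %d graphs over %d nodes, common total weight %.4g\n",
              length(object@graphs), length(nodes(object)), object@commonTotal))
  a <- object@alphas
  if (all(is.na(a))) cat("  conductance thresholds: not set (see learnAlphas)\n")
  else cat("  conductance thresholds:", paste(signif(a, 3), collapse = ", "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection '%s': %d sets, sizes %d-%d\n",
              object@className, length(object@sets),
              min(lengths(object@sets)), max(lengths(object@sets))))
})

setMethod("show", "Cut", function(object) {
  cat(sprintf("Cut from '%s'%s: |S| = %d vs %d\n", object@source,
              if (is.na(object@scale)) "" else sprintf(" (scale %g)", object@scale),
              length(object@side), length(object@otherSide)))
  if (length(object@conductances))
    cat("  conductances:",
        paste(sprintf("%s=%.4g", names(object@conductances), object@conductances),
              collapse = ", "), "\n")
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: n = %d, best prefix %d, phi = %.4g, lambda2 = %.4g\n",
              length(object@ordering), object@bestPrefix,
              object@cut@conductances[[1L]], object@lambda2))
})

setMethod("show", "ClusteringTree", function(object) {
  lv <- .treeLeafSets(object@root)
  cat(sprintf("ClusteringTree (%s mode): %d nodes, %d leaves (sizes %s)\n",
              object@mode, length(object@nodeSet), length(lv),
              paste(sort(lengths(lv), decreasing = TRUE), collapse = ", ")))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d clusters over %d nodes\n",
              length(object@clusters), length(nodes(object))))
  if (length(object@minModularity)) {
    k <- min(5L, length(object@clusters))
    for (i in seq_len(k))
      cat(sprintf("  rank %d: %d genes, min-modularity %.4g\n",
                  i, length(object@clusters[[i]]), object@minModularity[i]))
    if (length(object@clusters) > k) cat("  ...\n")
  }
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d nodes in %d clusters, %d graphs, kTotal %g, kOut %s\n",
    object@nNodes, object@nClusters, object@nGraphs, object@kTotal,
    paste(object@kOut, collapse = "/")))
})
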