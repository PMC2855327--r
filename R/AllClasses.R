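#' @import methods
#' @importFrom stats aggregate cor cor.test median phyper runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

#' Weighted undirected network over a fixed gene set
#'
#' A symmetric, non-negative edge weight function over an ordered set of gene
#' identifiers.  Self-loops are forbidden: the diagonal of the weight matrix
#' must be zero, so the incident weight of a node set is unambiguous.  This is
#' the unit on which all conductance and modularity computations operate.
#'
#' @slot weights numeric matrix, symmetric with zero diagonal and non-negative
#'   entries; dimnames carry the gene identifiers.
#' @slot name single character label for the network.
#' @seealso [weightedGraph()], [readEdgeList()], [coexpressionGraph()]
#' @export
setClass("WeightedGraph",
  representation(weights = "matrix", name = "character"))

setValidity("WeightedGraph", function(object) {
  W <- object@weights
  msg <- character()
  if (nrow(W) != ncol(W)) msg <- c(msg, "weight matrix must be square")
  if (is.null(rownames(W)) || is.null(colnames(W)))
    msg <- c(msg, "weight matrix must carry gene identifiers as dimnames")
  else if (!identical(rownames(W), colnames(W)))
    msg <- c(msg, "row and column gene identifiers differ")
  if (anyNA(W)) msg <- c(msg, "weights must not contain NA")
  else {
    if (any(W < 0)) msg <- c(msg, "negative edge weights are not allowed")
    if (nrow(W) > 0 && any(diag(W) != 0))
      msg <- c(msg, "self-loops (non-zero diagonal) are not allowed")
    if (max(abs(W - t(W))) > 1e-8 * max(1, max(abs(W))))
      msg <- c(msg, "weight matrix must be symmetric")
  }
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(msg)) msg else TRUE
})

#' Collection of networks over an identical gene set
#'
#' Holds k weighted networks over exactly the same ordered gene set, each
#' rescaled so that its total edge weight equals `commonTotal`.  Rescaling
#' leaves every cut conductance unchanged (conductance is scale-invariant) but
#' makes the aggregated inter-cluster edge cost comparable across networks.
#' The slot `alphas` carries the graph-specific conductance thresholds used by
#' the joint recursion; it is `NA` until supplied or learnt with
#' [learnAlphas()].
#'
#' @slot graphs list of [WeightedGraph-class] objects.
#' @slot commonTotal positive scalar; the shared total edge weight.
#' @slot alphas numeric vector of per-graph thresholds in (0,1), or `NA`.
#' @seealso [rescaleCollection()], [learnAlphas()], [jointClusterTree()]
#' @export
setClass("GraphCollection",
  representation(graphs = "list", commonTotal = "numeric", alphas = "numeric"))

setValidity("GraphCollection", function(object) {
  msg <- character()
  gs <- object@graphs
  if (length(gs) < 1L) msg <- c(msg, "at least one graph is required")
  if (!all(vapply(gs, is, TRUE, "WeightedGraph")))
    msg <- c(msg, "graphs must all be WeightedGraph objects")
  else {
    nds <- lapply(gs, function(g) rownames(g@weights))
    if (length(unique(nds)) > 1L)
      msg <- c(msg, "all graphs must share an identical, identically ordered gene set")
    tot <- vapply(gs, function(g) sum(g@weights) / 2, 0)
    ct <- object@commonTotal
    if (length(ct) != 1L || !is.finite(ct) || ct <= 0)
      msg <- c(msg, "commonTotal must be a positive scalar")
    else if (any(abs(tot - ct) > 1e-9 * ct))
      msg <- c(msg, "every graph's total edge weight must equal commonTotal (rel. tol 1e-9)")
  }
  a <- object@alphas
  if (!(length(a) == 1L && is.na(a)) && length(a) != length(gs))
    msg <- c(msg, "alphas must be NA or one threshold per graph")
  if (!all(is.na(a)) && any(!is.na(a) & (a <= 0 | a >= 1)))
    msg <- c(msg, "alphas must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Named collection of gene sets
#'
#' A flat list of named gene sets belonging to one reference class (for
#' example GO biological process terms, or transcription-factor perturbation
#' signatures).  Genes are plain identifiers; duplicates within a set collapse.
#'
#' @slot className single character label for the reference class.
#' @slot sets named list of character vectors, each non-empty.
#' @seealso [readGMT()], [hypergeomEnrich()]
#' @export
setClass("GeneSetCollection",
  representation(className = "character", sets = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@className) != 1L) msg <- c(msg, "className must be a single string")
  s <- object@sets
  if (is.null(names(s)) || any(!nzchar(names(s))))
    msg <- c(msg, "every gene set must be named")
  if (any(duplicated(names(s)))) msg <- c(msg, "gene set names must be unique")
  if (!all(vapply(s, is.character, TRUE)) || any(lengths(s) == 0L))
    msg <- c(msg, "gene sets must be non-empty character vectors")
  if (length(msg)) msg else TRUE
})

#' A bipartition of a node set
#'
#' A cut splits a node set C into two non-empty sides.  Cuts are annotated
#' with the conductance they achieve in each graph of interest (named numeric
#' vector), the label of the graph (input or mixture) that produced them, and
#' the mixture scale at which they were found (`NA` for cuts from the basic
#' algorithm or from a plain input graph).
#'
#' @slot side character vector, the node set S.
#' @slot otherSide character vector, C \ S.
#' @slot conductances named numeric vector of per-graph conductances in [0,1].
#' @slot source single character, label of the graph that produced the cut.
#' @slot scale numeric scalar, mixture scale s >= 1, or `NA`.
#' @export
setClass("Cut",
  representation(side = "character", otherSide = "character",
                 conductances = "numeric", source = "character",
                 scale = "numeric"))

setValidity("Cut", function(object) {
  msg <- character()
  if (length(object@side) == 0L || length(object@otherSide) == 0L)
    msg <- c(msg, "both sides of a cut must be non-empty")
  if (length(intersect(object@side, object@otherSide)))
    msg <- c(msg, "cut sides must be disjoint")
  cc <- object@conductances
  if (length(cc) && any(cc < -1e-12 | cc > 1 + 1e-12))
    msg <- c(msg, "recorded conductances must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Result of a spectral sweep over a graph
#'
#' The Fiedler vector of the degree-normalised Laplacian of the (induced)
#' graph orders the nodes; every prefix of that ordering is a candidate cut
#' and the minimum-conductance prefix is retained.  The sweep conductance
#' obeys the Cheeger bound phi <= sqrt(2 * lambda2).
#'
#' @slot ordering character vector, nodes sorted by Fiedler-vector value
#'   (ties broken lexicographically).
#' @slot bestPrefix integer in [1, n-1]; the chosen split position.
#' @slot cut the resulting [Cut-class].
#' @slot lambda2 second-smallest eigenvalue of the normalised Laplacian
#'   (0 for disconnected subgraphs, which short-circuit to a component split).
#' @slot profile numeric vector of prefix conductances (the sweep profile).
#' @seealso [approxSparsestCut()]
#' @export
setClass("SweepResult",
  representation(ordering = "character", bestPrefix = "integer",
                 cut = "Cut", lambda2 = "numeric", profile = "numeric"))

#' Binary clustering tree from the joint recursion
#'
#' Records every cut made by the recursion: each internal node holds its node
#' set, the chosen [Cut-class], the source graph and the mixture scale; leaves
#' are node sets in which no sparse-enough cut exists.  Leaves partition the
#' root node set exactly, and scales are non-decreasing from root to leaf.
#'
#' @slot root nested list representation of the tree; every node is a list
#'   with elements `set`, and for internal nodes `cut`, `left`, `right`.
#' @slot nodeSet character vector, the full gene universe V.
#' @slot alphas per-graph conductance thresholds the tree was grown with.
#' @slot mode `"basic"` or `"scaling"`.
#' @seealso [jointClusterTree()], [parseTree()], [treeLeaves()]
#' @export
setClass("ClusteringTree",
  representation(root = "list", nodeSet = "character",
                 alphas = "numeric", mode = "character"))

setValidity("ClusteringTree", function(object) {
  lv <- .treeLeafSets(object@root)
  all_nodes <- sort(unlist(lv, use.names = FALSE))
  if (!identical(all_nodes, sort(object@nodeSet)))
    return("tree leaves must partition the node set exactly")
  TRUE
})

#' Disjoint clusters covering the gene universe
#'
#' Clusters are stored in rank order: rank 1 is the cluster with the largest
#' min-modularity (the minimum over graphs of the cluster's Newman-style
#' modularity).  A partition built without a scoring collection (for example
#' the planted truth of a simulation) carries empty score slots.
#'
#' @slot clusters list of character vectors, disjoint, covering V, ordered by
#'   decreasing min-modularity when scored.
#' @slot perGraphModularity numeric matrix, clusters x graphs.
#' @slot minModularity numeric vector, row-wise minimum of the above.
#' @seealso [parseTree()], [scorePartition()], [jaccardIndex()]
#' @export
setClass("Partition",
  representation(clusters = "list", perGraphModularity = "matrix",
                 minModularity = "numeric"))

setValidity("Partition", function(object) {
  msg <- character()
  cl <- object@clusters
  if (length(cl) == 0L) msg <- c(msg, "a partition needs at least one cluster")
  all_nodes <- unlist(cl, use.names = FALSE)
  if (anyDuplicated(all_nodes)) msg <- c(msg, "clusters must be disjoint")
  nq <- length(object@minModularity)
  if (nq) {
    if (nq != length(cl))
      msg <- c(msg, "one min-modularity score per cluster is required")
    else {
      mm <- apply(object@perGraphModularity, 1L, min)
      if (max(abs(mm - object@minModularity)) > 1e-9)
        msg <- c(msg, "minModularity must equal the row-wise minimum of perGraphModularity")
      if (is.unsorted(rev(object@minModularity)))
        msg <- c(msg, "clusters must be ordered by decreasing min-modularity")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the planted-partition simulator
#'
#' Each of `nGraphs` unit-weight random graphs over `nNodes` nodes receives
#' the same planted clustering of `nClusters` equal-sized clusters.  Every
#' node has expected total degree `kTotal` of which expected `kOut` edges
#' leave its cluster, so kOut/kTotal is the false positive rate of a graph.
#' `kOut` may be a vector of length `nGraphs` for asymmetric noise designs.
#'
#' @slot nNodes,nClusters,kTotal,kOut,nGraphs numeric configuration values.
#' @seealso [simConfig()], [simulateGraphs()]
#' @export
setClass("SimConfig",
  representation(nNodes = "numeric", nClusters = "numeric",
                 kTotal = "numeric", kOut = "numeric", nGraphs = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  n <- object@nNodes; m <- object@nClusters
  if (n %% m != 0) msg <- c(msg, "nNodes must be divisible by nClusters")
  if (any(object@kOut < 0) || any(object@kOut > object@kTotal))
    msg <- c(msg, "kOut must lie in [0, kTotal]")
  if (object@kTotal >= n) msg <- c(msg, "kTotal must be below nNodes")
  if (!(length(object@kOut) %in% c(1L, object@nGraphs)))
    msg <- c(msg, "kOut must have length 1 or nGraphs")
  csize <- n / m
  pin <- (object@kTotal - object@kOut) / (csize - 1)
  if (any(pin > 1))
    msg <- c(msg, sprintf(
      "infeasible within-cluster edge probability %.3f > 1 (kTotal=%g, kOut=%g, cluster size %g)",
      max(pin), object@kTotal, object@kOut[which.max(pin)], csize))
  if (length(msg)) msg else TRUE
})
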