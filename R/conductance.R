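# Internal workhorses operate on plain weight matrices and integer indices;
# the exported surface takes WeightedGraph / GraphCollection plus gene names.

.idx <- function(g, set) {
  i <- match(set, rownames(g@weights))
  if (anyNA(i)) stop("node(s) not in graph: ",
                     paste(utils::head(set[is.na(i)], 5L), collapse = ", "),
                     call. = FALSE)
  i
}

# conductance of bipartition (a, b) of the node set a U b, on the subgraph
# induced by a U b; zero when the denominator vanishes
.phi <- function(W, a, b) {
  Wc <- W[c(a, b), c(a, b), drop = FALSE]
  na <- length(a)
  cross <- sum(Wc[seq_len(na), na + seq_along(b)])
  vola <- sum(Wc[seq_len(na), ])
  volb <- sum(Wc) - vola
  den <- min(vola, volb)
  if (den <= 0) return(0)
  min(1, cross / den)
}

.treeLeafSets <- function(node) {
  if (is.null(node$left)) return(list(node$set))
  c(.treeLeafSets(node$left), .treeLeafSets(node$right))
}

#' Total edge weight between two disjoint node sets
#'
#' @param g a [WeightedGraph-class].
#' @param A,B disjoint character vectors of node identifiers.
#' @return Sum of the weights of all edges with one endpoint in `A` and the
#'   other in `B`.
#' @export
crossingWeight <- function(g, A, B) {
  if (length(intersect(A, B))) stop("A and B must be disjoint", call. = FALSE)
  sum(g@weights[.idx(g, A), .idx(g, B)])
}

#' Total weight incident at a node set
#'
#' Sums edge weights over all edges touching `S`; an edge with both endpoints
#' in `S` is counted once per endpoint (handshake convention), so the incident
#' weight of the whole node set is twice the total edge weight.
#'
#' @param g a [WeightedGraph-class].
#' @param S character vector of node identifiers (may be empty).
#' @return Non-negative scalar.
#' @export
incidentWeight <- function(g, S) {
  if (!length(S)) return(0)
  sum(g@weights[.idx(g, S), ])
}

#' Conductance of a cut
#'
#' The conductance of the cut `(S, C \ S)` in the subgraph induced by `C` is
#' the weight of edges crossing the cut divided by the smaller side's incident
#' weight (both measured inside `C`).  The ratio is defined as zero when its
#' denominator is zero, and is invariant to rescaling all edge weights.
#'
#' @param g a [WeightedGraph-class].
#' @param S non-empty proper subset of `C`.
#' @param C the node set being split; defaults to all nodes of `g`.
#' @return Conductance in [0, 1].
#' @export
cutConductance <- function(g, S, C = nodes(g)) {
  if (!length(S) || !all(S %in% C) || length(S) >= length(C))
    stop("S must be a non-empty strict subset of C", call. = FALSE)
  .phi(g@weights, .idx(g, S), .idx(g, setdiff(C, S)))
}

#' Conductance of a cluster
#'
#' The minimum conductance over every bipartition of `C` (on the subgraph
#' induced by `C`).  `"exhaustive"` mode enumerates all 2^(|C|-1) - 1 cuts and
#' is limited to |C| <= 20; `"spectral-bound"` mode returns the best spectral
#' sweep cut, an upper bound on the true minimum.
#'
#' @param g a [WeightedGraph-class].
#' @param C node set with at least 2 members.
#' @param mode `"exhaustive"` or `"spectral-bound"`.
#' @return Minimum (or bounded) conductance.
#' @export
clusterConductance <- function(g, C = nodes(g),
                               mode = c("exhaustive", "spectral-bound")) {
  mode <- match.arg(mode)
  n <- length(C)
  if (n < 2L) stop("a cluster of size >= 2 is required", call. = FALSE)
  W <- g@weights[.idx(g, C), .idx(g, C), drop = FALSE]
  if (mode == "exhaustive") {
    if (n > 20L)
      stop("exhaustive enumeration is limited to 20 nodes (2^(n-1) cuts)",
           call. = FALSE)
    d <- rowSums(W)
    volT <- sum(d)
    best <- Inf
    for (m in seq_len(2L^(n - 1L) - 1L)) {
      side <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L)
      vola <- sum(d[side])
      den <- min(vola, volT - vola)
      cross <- sum(W[side, -side, drop = FALSE])
      phi <- if (den <= 0) 0 else cross / den
      if (phi < best) best <- phi
    }
    min(1, best)
  } else {
    if (all(W == 0)) return(0)
    sw <- .sweepCut(W)
    sw$phi
  }
}

#' Conductance of a clustering in one graph
#'
#' The minimum conductance over all clusters of a partition, measured in
#' graph `graphIndex` of the collection.  Singleton clusters contain no cut
#' and are skipped; an all-singleton partition has (vacuous) conductance 1.
#' Clusters of at most 20 nodes are scored exhaustively, larger ones by the
#' spectral bound; the attribute `"mode"` records which mode produced the
#' minimum.
#'
#' @param gc a [GraphCollection-class].
#' @param p a [Partition-class] (or list of node sets) over the collection's
#'   node set.
#' @param graphIndex which graph to measure in.
#' @return Scalar conductance with attribute `"mode"`.
#' @export
clusteringConductance <- function(gc, p, graphIndex = 1L) {
  cl <- if (is(p, "Partition")) p@clusters else p
  if (!setequal(unlist(cl), nodes(gc)))
    stop("partition does not cover the collection's node set", call. = FALSE)
  g <- gc@graphs[[graphIndex]]
  vals <- numeric(); modes <- character()
  for (C in cl) {
    if (length(C) < 2L) next
    mode <- if (length(C) <= 20L) "exhaustive" else "spectral-bound"
    vals <- c(vals, clusterConductance(g, C, mode))
    modes <- c(modes, mode)
  }
  if (!length(vals)) return(structure(1, mode = "vacuous"))
  structure(min(vals), mode = modes[which.min(vals)])
}

#' Aggregated inter-cluster edge cost
#'
#' The total weight of edges whose endpoints fall in different clusters,
#' summed over all graphs, as a fraction of the total edge weight of all
#' graphs.  With graphs rescaled to a common total this is the epsilon of an
#' (alpha, epsilon) simultaneous clustering.
#'
#' @param gc a [GraphCollection-class].
#' @param p a [Partition-class] (or list of node sets).
#' @return Cost in [0, 1].
#' @export
interclusterCost <- function(gc, p) {
  cl <- if (is(p, "Partition")) p@clusters else p
  nm <- nodes(gc)
  lab <- integer(length(nm)); names(lab) <- nm
  for (i in seq_along(cl)) lab[cl[[i]]] <- i
  same <- outer(lab, lab, "==")
  crossW <- vapply(gc@graphs, function(g) sum(g@weights[!same]) / 2, 0)
  totW <- vapply(gc@graphs, totalWeight, 0)
  sum(crossW) / sum(totW)
}
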