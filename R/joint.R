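# The joint recursion: at every node set, approximate the sparsest cut in
# each input graph (basic mode) or in each mixture graph at the current scale
# (scaling mode), refine each cut by max-flow, keep the cuts that are
# sparse-enough for their own graph, and recurse on the best of them.

# conductance of the bipartition (a, rest) of the full matrix W
.phiIdx <- function(W, a) {
  vola <- sum(W[a, ])
  volT <- sum(W)
  cross <- vola - sum(W[a, a])
  den <- min(vola, volT - vola)
  if (den <= 0) return(0)
  min(1, cross / den)
}

# canonical string key of a cut for lexicographic tie-breaking
.cutKey <- function(nm, a) {
  s1 <- paste(sort(nm[a]), collapse = "\r")
  s2 <- paste(sort(nm[-a]), collapse = "\r")
  min(s1, s2)
}

# rank candidate cuts: most input graphs where sparse-enough, then least
# aggregated crossing-cost fraction, then source graph index, then the
# lexicographically smallest side
.pickBest <- function(cands, WsumInd, alphas, nm) {
  count <- vapply(cands, function(cn) sum(cn$phiIn < alphas), 0L)
  totSum <- sum(WsumInd) / 2
  cost <- vapply(cands, function(cn) {
    a <- cn$a
    (sum(WsumInd[a, ]) - sum(WsumInd[a, a])) / max(totSum, .Machine$double.eps)
  }, 0)
  key <- vapply(cands, function(cn) .cutKey(nm, cn$a), "")
  src <- vapply(cands, function(cn) cn$src, 0L)
  cands[[order(-count, cost, src, key)[1L]]]
}

.leafNode <- function(set) list(set = set, cut = NULL, left = NULL, right = NULL)

# One round of candidate generation.  `mixScale` = NA for basic mode (cuts
# come from the input graphs themselves), otherwise the current scale s.
.candidates <- function(WsInd, WsumInd, alphas, mixScale) {
  k <- length(WsInd)
  cands <- list()
  for (i in seq_len(k)) {
    Wsrc <- if (is.na(mixScale)) WsInd[[i]] else
      WsInd[[i]] + (WsumInd - WsInd[[i]]) / mixScale
    if (all(Wsrc == 0)) next
    sw <- .sweepCut(Wsrc)
    a0 <- match(sw$ordering[seq_len(sw$bestPrefix)], rownames(Wsrc))
    a <- .mqi(Wsrc, a0)
    if (!length(a) || length(a) == nrow(Wsrc)) a <- a0
    if (.phiIdx(Wsrc, a) > .phiIdx(Wsrc, a0)) a <- a0  # refinement is monotone
    phiSrc <- .phiIdx(Wsrc, a)
    if (!(phiSrc < alphas[i])) next
    phiIn <- vapply(WsInd, .phiIdx, 0, a = a)
    cands[[length(cands) + 1L]] <-
      list(a = a, phiIn = phiIn, phiSrc = phiSrc, src = i, scale = mixScale)
  }
  cands
}

# Recursive tree construction.  `si` indexes into `schedule`; si >
# length(schedule) (or a NULL schedule) means basic mode.  `collect` is an
# optional environment accumulating the conductances of accepted cuts (used
# by learnAlphas).
.jcRecurse <- function(WsFull, graphNames, alphas, idx, minSize, schedule, si,
                       collect = NULL) {
  nmAll <- rownames(WsFull[[1L]])
  set <- nmAll[idx]
  if (length(idx) < 2L || length(idx) < minSize) return(.leafNode(set))
  WsInd <- lapply(WsFull, function(W) W[idx, idx, drop = FALSE])
  WsumInd <- Reduce(`+`, WsInd)
  if (all(WsumInd == 0)) return(.leafNode(set))
  nm <- rownames(WsInd[[1L]])

  scaling <- !is.null(schedule) && si <= length(schedule)
  cands <- list()
  if (scaling) {
    while (si <= length(schedule)) {
      cands <- .candidates(WsInd, WsumInd, alphas, schedule[si])
      if (length(cands)) break
      si <- si + 1L
    }
  }
  if (!length(cands))  # basic mode, or scaling schedule exhausted
    cands <- .candidates(WsInd, WsumInd, alphas, NA_real_)
  if (!length(cands)) return(.leafNode(set))

  best <- .pickBest(cands, WsumInd, alphas, nm)
  if (!is.null(collect)) collect$phi <- c(collect$phi, best$phiSrc)
  side <- nm[best$a]
  other <- setdiff(set, side)
  srcName <- graphNames[best$src]
  cut <- new("Cut", side = side, otherSide = other,
             conductances = stats::setNames(pmin(pmax(best$phiIn, 0), 1),
                                            graphNames),
             source = if (is.na(best$scale)) srcName else
               sprintf("mixture(%s, s=%g)", srcName, best$scale),
             scale = best$scale)
  list(set = set, cut = cut,
       left = .jcRecurse(WsFull, graphNames, alphas, idx[nm %in% side],
                         minSize, schedule, si, collect),
       right = .jcRecurse(WsFull, graphNames, alphas, idx[nm %in% other],
                          minSize, schedule, si, collect))
}

#' Sum graph of a collection
#'
#' Edge weights are the sum of the corresponding edge weights in all graphs;
#' with a rescaled collection its total weight is k times the common total.
#'
#' @param gc a [GraphCollection-class].
#' @return A [WeightedGraph-class].
#' @export
sumGraph <- function(gc) {
  weightedGraph(Reduce(`+`, lapply(gc@graphs, slot, "weights")), "sum")
}

#' Min graph of a collection
#'
#' Edge weights are the pointwise minimum over all graphs; the min graph is
#' the certificate graph for the inter-cluster cost bound of the joint
#' recursion.  A min graph with no edges at all (disjoint edge sets) is
#' flagged with a warning.
#'
#' @param gc a [GraphCollection-class].
#' @return A [WeightedGraph-class].
#' @export
minGraph <- function(gc) {
  W <- Reduce(pmin, lapply(gc@graphs, slot, "weights"))
  if (all(W == 0))
    warning("min graph is empty: the input graphs share no edges", call. = FALSE)
  weightedGraph(W, "min")
}

#' Mixture graph of one input graph with the downscaled rest
#'
#' The mixture of graph i at scale s has weights `W_i + (1/s) * sum_{j != i}
#' W_j` (restricted to the subgraph induced by `C`).  At s = 1 every mixture
#' equals the sum graph; as s grows the mixture converges to graph i.
#'
#' @param gc a [GraphCollection-class].
#' @param i index of the base graph.
#' @param s scale, s >= 1.
#' @param C node subset; defaults to the full node set.
#' @return A [WeightedGraph-class] over `C`.
#' @export
mixtureGraph <- function(gc, i, s, C = nodes(gc)) {
  if (s < 1) stop("mixture scale must be >= 1", call. = FALSE)
  ci <- match(C, nodes(gc))
  if (anyNA(ci)) stop("C contains nodes outside the collection", call. = FALSE)
  Ws <- lapply(gc@graphs, function(g) g@weights[ci, ci, drop = FALSE])
  Wm <- Ws[[i]] + (Reduce(`+`, Ws) - Ws[[i]]) / s
  weightedGraph(Wm, sprintf("mixture(%s, s=%g)", gc@graphs[[i]]@name, s))
}

#' Is a cut sparse-enough in a graph?
#'
#' A cut is sparse-enough when its conductance, measured in `g` on the
#' subgraph induced by `C`, is strictly below the threshold `alpha`.  This is
#' the recursion's continuation test.
#'
#' @param g a [WeightedGraph-class].
#' @param cut a [Cut-class].
#' @param C the node set being split.
#' @param alpha conductance threshold in (0,1).
#' @return Logical.
#' @export
sparseEnough <- function(g, cut, C = c(cut@side, cut@otherSide), alpha) {
  cutConductance(g, cut@side, C) < alpha
}

#' Select the best cut among sparse-enough candidates
#'
#' Ranks candidate cuts (each annotated with its conductance in every input
#' graph of the collection) by the number of input graphs in which they are
#' sparse-enough; ties break toward the cut with the least aggregated
#' crossing-weight fraction, then the lowest source graph index, then the
#' lexicographically smallest side.
#'
#' @param candidates list of [Cut-class] objects whose `conductances` slot is
#'   named by the collection's graph names.
#' @param gc a [GraphCollection-class] with thresholds set.
#' @param C the node set being split.
#' @return The winning [Cut-class], or `NULL` for an empty candidate list.
#' @export
bestCut <- function(candidates, gc, C) {
  if (!length(candidates)) return(NULL)
  a <- gc@alphas
  if (all(is.na(a))) stop("collection has no conductance thresholds", call. = FALSE)
  gn <- vapply(gc@graphs, graphName, "")
  ci <- match(C, nodes(gc))
  WsInd <- lapply(gc@graphs, function(g) g@weights[ci, ci, drop = FALSE])
  WsumInd <- Reduce(`+`, WsInd)
  nm <- C
  cands <- lapply(seq_along(candidates), function(l) {
    cut <- candidates[[l]]
    src <- match(cut@source, gn)
    list(a = match(cut@side, C), phiIn = cut@conductances[gn],
         src = if (is.na(src)) l else src, scale = cut@scale, orig = cut)
  })
  .pickBest(cands, WsumInd, a, nm)$orig
}

#' Grow the joint clustering tree over multiple networks
#'
#' Recursively removes sparse-enough approximate sparsest cuts from the
#' collection until only well-connected node sets remain.  In `"basic"` mode
#' each input graph proposes its own sweep cut (flow-refined) and a cut
#' qualifies when its conductance in its own graph falls strictly below that
#' graph's threshold.  In `"scaling"` mode cuts are proposed by mixture
#' graphs: at the current scale s every graph i proposes the refined sweep
#' cut of `W_i + (1/s) * sum_{j != i} W_j`, which qualifies when its
#' conductance in that mixture is strictly below alpha_i.  When no mixture cut
#' qualifies the scale advances along `sSchedule`; when the schedule is
#' exhausted the node set falls back to basic mode.  Scales are carried down
#' each branch and never decrease.  Among qualifying cuts the one
#' sparse-enough in the most input graphs wins (see [bestCut()]).
#'
#' @param gc a [GraphCollection-class] with per-graph thresholds set (via
#'   `alphas<-` or [learnAlphas()]).
#' @param mode `"scaling"` (default, the practical heuristic) or `"basic"`.
#' @param sSchedule increasing scale schedule; default geometric 1,2,...,64.
#' @param seed kept for interface stability; the recursion is deterministic.
#' @param minSize node sets smaller than this are leaves (default 2; size
#'   filtering for reporting happens at parse/evaluation time, not here).
#' @return A [ClusteringTree-class].
#' @seealso [parseTree()], [learnAlphas()]
#' @export
jointClusterTree <- function(gc, mode = c("scaling", "basic"),
                             sSchedule = 2^(0:6), seed = 0L, minSize = 2L) {
  mode <- match.arg(mode)
  a <- gc@alphas
  if (all(is.na(a)))
    stop("conductance thresholds are not set; run learnAlphas() first ",
         "or assign alphas(gc) <- ...", call. = FALSE)
  if (mode == "scaling" && is.unsorted(sSchedule))
    stop("sSchedule must be non-decreasing", call. = FALSE)
  Ws <- lapply(gc@graphs, slot, "weights")
  gn <- vapply(gc@graphs, graphName, "")
  schedule <- if (mode == "scaling") sSchedule else NULL
  root <- .jcRecurse(Ws, gn, a, seq_along(nodes(gc)), as.integer(minSize),
                     schedule, 1L)
  new("ClusteringTree", root = root, nodeSet = nodes(gc), alphas = a,
      mode = mode)
}

#' Learn graph-specific conductance thresholds
#'
#' For each graph independently, the single-graph recursion is run with a
#' permissive threshold (0.5) down to small node sets and the conductances of
#' all accepted cuts are collected; alpha_i is the median of that empirical
#' distribution, clamped to [0.01, 0.5].  The full distributions are attached
#' as attribute `"distributions"` for audit.
#'
#' @param gc a [GraphCollection-class].
#' @param seed kept for interface stability; the procedure is deterministic.
#' @param minSize recursion floor (default 2).
#' @param permissive exploration threshold (default 0.5).
#' @return Named numeric vector of per-graph thresholds with attribute
#'   `"distributions"`.
#' @export
learnAlphas <- function(gc, seed = 0L, minSize = 2L, permissive = 0.5) {
  gn <- vapply(gc@graphs, graphName, "")
  dists <- vector("list", length(gc@graphs))
  out <- numeric(length(gc@graphs))
  for (i in seq_along(gc@graphs)) {
    W <- gc@graphs[[i]]@weights
    collect <- new.env(parent = emptyenv())
    collect$phi <- numeric()
    .jcRecurse(list(W), gn[i], permissive, seq_len(nrow(W)),
               as.integer(minSize), NULL, 1L, collect)
    if (!length(collect$phi))
      stop("graph '", gn[i], "' admits no cut below the permissive threshold; ",
           "cannot learn a conductance threshold", call. = FALSE)
    dists[[i]] <- collect$phi
    out[i] <- min(max(median(collect$phi), 0.01), 0.5)
  }
  structure(stats::setNames(out, gn), distributions = dists)
}
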