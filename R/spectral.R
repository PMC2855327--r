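# Spectral sweep approximation of the sparsest cut, plus MQI-style flow
# refinement.  Everything here is deterministic: eigenvectors come from a
# dense symmetric solver, ties in the Fiedler ordering break lexicographically
# by node name, and the flow improvement is a deterministic max-flow loop.

.components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Sweep over the Fiedler ordering of the normalised Laplacian of W (a plain
# induced weight matrix with dimnames).  Disconnected subgraphs short-circuit
# to a zero-conductance component split before any eigensolve.
.sweepCut <- function(W) {
  n <- nrow(W)
  nm <- rownames(W)
  if (n < 2L) stop("cannot cut fewer than 2 nodes", call. = FALSE)
  if (all(W == 0)) stop("induced subgraph has no edges", call. = FALSE)
  W <- W / sum(W)   # scale-invariant; proportional inputs sweep identically
  d <- rowSums(W)
  comp <- .components(W)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    k <- which(sizes == min(sizes))
    if (length(k) > 1L)  # ties: component containing the smallest node name
      k <- k[order(vapply(k, function(c) min(nm[comp == c]), ""))]
    inside <- comp == k[1L]
    ord <- c(order(!inside, nm))  # chosen component first, names break ties
    return(list(ordering = nm[ord], bestPrefix = sum(inside), phi = 0,
                lambda2 = 0, profile = rep(NA_real_, n - 1L)))
  }
  s <- sqrt(d)
  L <- -W / outer(s, s)
  diag(L) <- 1
  e <- eigen(L, symmetric = TRUE)
  lambda2 <- max(e$values[n - 1L], 0)
  y <- e$vectors[, n - 1L] / s
  ord <- order(y, nm)
  Wo <- W[ord, ord]
  dd <- d[ord]
  vol <- cumsum(dd)
  volT <- vol[n]
  # weight from node j back into the prefix 1..j-1
  wBack <- rowSums(Wo * lower.tri(Wo))
  cross <- pmax(cumsum(dd - 2 * wBack), 0)[seq_len(n - 1L)]
  den <- pmin(vol[seq_len(n - 1L)], volT - vol[seq_len(n - 1L)])
  phi <- ifelse(den > 0, cross / den, 0)
  best <- which.min(phi)
  list(ordering = nm[ord], bestPrefix = best, phi = min(1, phi[best]),
       lambda2 = lambda2, profile = phi)
}

#' Approximate the sparsest cut of a graph by a spectral sweep
#'
#' Computes the Fiedler vector of the degree-normalised Laplacian of the
#' subgraph induced by `C`, sorts nodes by eigenvector value (ties broken
#' lexicographically by node name), evaluates all n-1 prefix cuts and returns
#' the one of minimum conductance.  Its conductance is an upper bound on the
#' true sparsest-cut conductance and obeys the Cheeger sweep bound
#' phi <= sqrt(2 * lambda2).  If the induced subgraph is disconnected, the
#' zero-conductance component split is returned directly without an
#' eigensolve.
#'
#' @param g a [WeightedGraph-class].
#' @param C node set to split; defaults to all nodes.  The induced subgraph
#'   must contain at least one edge.
#' @param seed unused placeholder kept for interface stability; the
#'   computation is fully deterministic.
#' @return A [SweepResult-class] whose cut records the conductance achieved
#'   in `g` (induced on `C`).
#' @export
approxSparsestCut <- function(g, C = nodes(g), seed = 0L) {
  W <- g@weights[.idx(g, C), .idx(g, C), drop = FALSE]
  sw <- .sweepCut(W)
  side <- sw$ordering[seq_len(sw$bestPrefix)]
  cut <- new("Cut", side = side,
             otherSide = setdiff(C, side),
             conductances = stats::setNames(sw$phi, g@name),
             source = g@name, scale = NA_real_)
  new("SweepResult", ordering = sw$ordering,
      bestPrefix = as.integer(sw$bestPrefix), cut = cut,
      lambda2 = sw$lambda2, profile = sw$profile)
}

# One MQI pass: shrink the seed side A towards a subset with a smaller
# quotient cut c(A')/vol(A') via repeated max-flows.  Returns integer indices
# of the refined side.
.mqiRefine <- function(W, d, A, maxIter = 20L) {
  n <- nrow(W)
  volA <- sum(d[A])
  B <- setdiff(seq_len(n), A)
  cA <- sum(W[A, B])
  if (volA <= 0 || cA <= 0) return(A)
  for (it in seq_len(maxIter)) {
    q <- cA / volA
    m <- length(A)
    if (m <= 1L) break
    bw <- rowSums(W[A, B, drop = FALSE])          # boundary weight per node
    Wi <- W[A, A, drop = FALSE]
    eidx <- which(Wi > 0 & upper.tri(Wi), arr.ind = TRUE)
    src <- m + 1L; snk <- m + 2L
    from <- c(eidx[, 1L], rep(src, sum(bw > 0)), seq_len(m))
    to   <- c(eidx[, 2L], which(bw > 0), rep(snk, m))
    cap  <- c(Wi[eidx], bw[bw > 0], q * d[A])
    gr <- igraph::make_graph(as.vector(rbind(from, to)), n = m + 2L,
                             directed = FALSE)
    mf <- igraph::max_flow(gr, source = src, target = snk, capacity = cap)
    if (mf$value >= cA * (1 - 1e-12)) break
    # a min cut with sink side T' (within A) has capacity
    # c(T') + q * (vol(A) - vol(T')), so capacity < cA iff c(T')/vol(T') < q:
    # the sink side is the improved seed set
    snkSide <- if (snk %in% as.integer(mf$partition2)) mf$partition2 else mf$partition1
    newA <- A[intersect(seq_len(m), as.integer(snkSide))]
    if (!length(newA) || length(newA) == length(A)) break
    A <- newA
    B <- setdiff(seq_len(n), A)
    volA <- sum(d[A])
    cA <- sum(W[A, B])
    if (cA <= 0 || volA <= 0) break
  }
  A
}

# Flow refinement of a bipartition: run the quotient improvement seeded from
# each side of the cut and keep the lowest-conductance result; never worse
# than the input cut.  Weights are normalised to unit total so that
# proportional graphs refine identically (conductance is scale-invariant).
.mqi <- function(W, side, maxIter = 20L) {
  W <- W / sum(W)
  n <- nrow(W)
  d <- rowSums(W)
  volT <- sum(d)
  phi <- function(a) {
    vola <- sum(d[a]); cross <- vola - sum(W[a, a])
    den <- min(vola, volT - vola)
    if (den <= 0) 0 else cross / den
  }
  best <- sort(side)
  bestPhi <- phi(best)
  # alternate seeding from both sides until neither improves (fixed point)
  for (round in seq_len(10L)) {
    cands <- list(.mqiRefine(W, d, best, maxIter),
                  .mqiRefine(W, d, setdiff(seq_len(n), best), maxIter))
    cands <- cands[vapply(cands, function(a)
      length(a) > 0 && length(a) < n, TRUE)]
    if (!length(cands)) break
    phis <- vapply(cands, phi, 0)
    if (min(phis) >= bestPhi - 1e-13) break
    best <- sort(cands[[which.min(phis)]])
    bestPhi <- min(phis)
  }
  best
}

#' Improve a cut by flow-based local refinement
#'
#' Max-flow quotient-cut improvement (MQI-style): the smaller side of the cut
#' (by incident weight) seeds a parametric max-flow search for a subset with a
#' strictly smaller quotient, iterated to convergence (at most 20 max-flow
#' rounds).  The returned cut's conductance in `g` never exceeds the input
#' cut's; when no improvement exists the input cut is returned unchanged.
#'
#' @param g a [WeightedGraph-class].
#' @param cut a [Cut-class] over `C`.
#' @param C the node set being split; defaults to the union of the cut sides.
#' @return A [Cut-class] with conductance annotation for `g`.
#' @export
improveCut <- function(g, cut, C = c(cut@side, cut@otherSide)) {
  if (!setequal(c(cut@side, cut@otherSide), C))
    stop("cut sides must partition C", call. = FALSE)
  ci <- .idx(g, C)
  W <- g@weights[ci, ci, drop = FALSE]
  nm <- rownames(W)
  before <- .phi(W, match(cut@side, nm), match(cut@otherSide, nm))
  A <- .mqi(W, match(cut@side, nm))
  if (!length(A) || length(A) == length(C)) return(cut)
  side <- nm[A]
  after <- .phi(W, A, setdiff(seq_along(nm), A))
  if (after < before) {
    new("Cut", side = side, otherSide = setdiff(C, side),
        conductances = stats::setNames(after, g@name),
        source = cut@source, scale = cut@scale)
  } else {
    cut@conductances <- stats::setNames(before, g@name)
    cut
  }
}
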