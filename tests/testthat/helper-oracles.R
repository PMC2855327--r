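# Independent brute-force oracles.  These deliberately avoid the package's
# internal code paths: all arithmetic is done directly on plain matrices.

# conductance of the bipartition (side, rest) of the whole matrix W
oracle_phi <- function(W, side) {
  rest <- setdiff(seq_len(nrow(W)), side)
  cross <- 0
  for (i in side) for (j in rest) cross <- cross + W[i, j]
  vol_s <- sum(W[side, , drop = FALSE])
  vol_r <- sum(W[rest, , drop = FALSE])
  den <- min(vol_s, vol_r)
  if (den <= 0) 0 else cross / den
}

# exhaustive minimum-conductance over all bipartitions (node 1 fixed on one
# side to halve the enumeration)
oracle_min_conductance <- function(W) {
  n <- nrow(W)
  best <- Inf
  best_side <- NULL
  for (m in seq_len(2^(n - 1) - 1)) {
    side <- which(as.logical(bitwAnd(m, 2^(0:(n - 1)))))
    phi <- oracle_phi(W, side)
    if (phi < best) { best <- phi; best_side <- side }
  }
  list(phi = best, side = best_side)
}

# all frontiers of a nested-list tree (each frontier is a list of node sets)
oracle_frontiers <- function(node) {
  own <- list(list(node$set))
  if (is.null(node$left)) return(own)
  lf <- oracle_frontiers(node$left)
  rf <- oracle_frontiers(node$right)
  combos <- list()
  for (a in lf) for (b in rf) combos[[length(combos) + 1]] <- c(a, b)
  c(own, combos)
}

# best frontier score by full enumeration, scoring each set with score_fn
oracle_best_frontier <- function(root, score_fn) {
  fr <- oracle_frontiers(root)
  scores <- vapply(fr, function(f) sum(vapply(f, score_fn, 0)), 0)
  max(scores)
}

# exhaustive hypergeometric upper tail: fraction of all size-n subsets of
# 1..U whose overlap with a fixed size-K subset is >= ov
oracle_hyper_tail <- function(U, K, n, ov) {
  subsets <- utils::combn(U, n)
  hits <- colSums(subsets <= K)  # reference set = {1..K}
  mean(hits >= ov)
}

# all set partitions of 1..n (restricted growth strings)
oracle_set_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxb) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- split(seq_len(n), assign)
      return()
    }
    for (b in seq_len(maxb + 1)) rec(c(assign, b), max(maxb, b))
  }
  rec(integer(), 0L)
  out
}

# random binary tree over a node set, as the package's nested-list shape
random_tree <- function(set, seed) {
  set.seed(seed)
  rec <- function(s) {
    if (length(s) < 2 || runif(1) < 0.25)
      return(list(set = s, cut = NULL, left = NULL, right = NULL))
    k <- sample(seq_len(length(s) - 1), 1)
    sh <- sample(s)
    list(set = s, cut = NULL,
         left = rec(sort(sh[seq_len(k)])), right = rec(sort(sh[-seq_len(k)])))
  }
  rec(set)
}
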