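# Fixture graphs built in code.

mat_graph <- function(n, edges, nodes = letters[seq_len(n)], name = "fix") {
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in edges) {
    i <- match(e[[1]], nodes); j <- match(e[[2]], nodes)
    W[i, j] <- W[j, i] <- if (length(e) > 2) as.numeric(e[[3]]) else 1
  }
  weightedGraph(W, name)
}

triangle_graph <- function() {
  mat_graph(3, list(c("a", "b"), c("b", "c"), c("a", "c")), name = "triangle")
}

path_graph <- function(n) {
  nodes <- letters[seq_len(n)]
  mat_graph(n, lapply(seq_len(n - 1), function(i) c(nodes[i], nodes[i + 1])),
            nodes = nodes, name = "path")
}

# two unit triangles a-b-c and d-e-f joined by the unit bridge c-d; w(E) = 7
barbell_graph <- function() {
  mat_graph(6, list(c("a", "b"), c("b", "c"), c("a", "c"),
                    c("d", "e"), c("e", "f"), c("d", "f"),
                    c("c", "d")), name = "barbell")
}

two_triangles_graph <- function() {  # disconnected
  mat_graph(6, list(c("a", "b"), c("b", "c"), c("a", "c"),
                    c("d", "e"), c("e", "f"), c("d", "f")),
            name = "two-triangles")
}

# two m-cliques joined by a single unit bridge edge
clique_pair_graph <- function(m = 12, name = "cliques") {
  n <- 2L * m
  nodes <- sprintf("n%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  W[seq_len(m), seq_len(m)] <- 1
  W[m + seq_len(m), m + seq_len(m)] <- 1
  diag(W) <- 0
  W[m, m + 1L] <- W[m + 1L, m] <- 1
  weightedGraph(W, name)
}

# connected random weighted graph (retries until connected)
random_graph <- function(n, seed, p = 0.5, weighted = TRUE, name = NULL) {
  set.seed(seed)
  nodes <- sprintf("r%02d", seq_len(n))
  repeat {
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    ut <- upper.tri(W)
    on <- runif(sum(ut)) < p
    w <- if (weighted) round(runif(sum(ut), 0.1, 2), 3) else 1
    W[ut] <- on * w
    W <- W + t(W)
    if (max(jointclust:::.components(W)) == 1L && any(W > 0)) break
  }
  weightedGraph(W, name %||% sprintf("rand%d", seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

edge_list_file <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, "", collapse = "\t"), f)
  f
}
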