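#' Read a weighted edge list
#'
#' Reads a three-column TSV (`node_a`, `node_b`, `weight`) into a
#' [WeightedGraph-class].  Row orientation is ignored (edges are undirected),
#' duplicate pairs have their weights summed, comment lines starting with `#`
#' are skipped.  Negative weights and self-loop rows are format errors; edges
#' touching nodes outside a supplied universe are rejected.
#'
#' @param path path to the TSV file.
#' @param nodes optional character vector fixing the node universe (ordering
#'   is kept).  When `NULL`, the sorted union of endpoints is used.
#' @param header logical; does the file start with a header row?
#' @param name label for the resulting network (defaults to the file name).
#' @return A [WeightedGraph-class].
#' @seealso [writeEdgeList()], [rescaleCollection()]
#' @export
readEdgeList <- function(path, nodes = NULL, header = FALSE,
                         name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  if (!any(keep)) stop("edge list '", path, "' contains no edges", call. = FALSE)
  df <- tryCatch(
    read.delim(text = lines[keep], header = header, stringsAsFactors = FALSE,
               colClasses = c("character", "character", "numeric")),
    error = function(e) stop("cannot parse edge list '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("edge list '", path, "' contains no edges", call. = FALSE)
  if (ncol(df) < 3L) stop("edge list '", path, "' must have three columns", call. = FALSE)
  a <- df[[1L]]; b <- df[[2L]]; w <- df[[3L]]
  if (anyNA(w)) stop("non-numeric weight in edge list '", path, "'", call. = FALSE)
  if (any(w < 0)) stop("negative edge weight at line ", which(w < 0)[1L],
                       " of '", path, "'", call. = FALSE)
  loops <- which(a == b)
  if (length(loops)) stop("self-loop at line ", loops[1L], " of '", path,
                          "' (", a[loops[1L]], ")", call. = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(a, b)))
  else {
    bad <- setdiff(unique(c(a, b)), nodes)
    if (length(bad)) stop("edge endpoints outside the supplied node universe: ",
                          paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  i <- match(a, nodes); j <- match(b, nodes)
  lo <- pmin(i, j); hi <- pmax(i, j)
  agg <- rowsum(w, group = (lo - 1) * n + hi)
  key <- as.numeric(rownames(agg))
  ii <- floor((key - 1) / n) + 1; jj <- key - (ii - 1) * n
  W[cbind(ii, jj)] <- agg[, 1L]
  W[cbind(jj, ii)] <- agg[, 1L]
  weightedGraph(W, name)
}

#' Write a weighted edge list
#'
#' Writes the non-zero edges of a network as a three-column TSV in canonical
#' node-pair order (so `readEdgeList(writeEdgeList(g))` reproduces `g`
#' exactly).
#'
#' @param g a [WeightedGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  W <- g@weights
  nm <- rownames(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(a = nm[idx[, 1L]], b = nm[idx[, 2L]], w = W[idx])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a coexpression network from an expression matrix
#'
#' The edge weight between two genes is the absolute value of the Pearson
#' correlation coefficient between their expression profiles, giving a
#' complete weighted graph with weights in [0, 1] (diagonal excluded).
#'
#' @param expr numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns; at least 3 samples.
#' @param dropConstant drop genes with zero expression variance instead of
#'   raising an error.
#' @param name label for the network.
#' @return A [WeightedGraph-class] over the (remaining) genes.
#' @export
coexpressionGraph <- function(expr, dropConstant = FALSE, name = "coexpression") {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L)
    stop("at least 3 samples are required to estimate correlations", call. = FALSE)
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames", call. = FALSE)
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    if (dropConstant) expr <- expr[v > 0, , drop = FALSE]
    else stop("zero-variance expression for gene(s): ",
              paste(utils::head(rownames(expr)[v == 0], 5L), collapse = ", "),
              call. = FALSE)
  }
  W <- abs(cor(t(expr)))
  diag(W) <- 0
  weightedGraph(W, name)
}

#' Read a gene x sample expression matrix
#'
#' TSV with gene identifiers in the first column and one column per sample.
#'
#' @param path file path.
#' @param header logical, defaults to `TRUE`.
#' @return Numeric matrix with gene rownames.
#' @export
readExpression <- function(path, header = TRUE) {
  df <- read.delim(path, header = header, stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Rescale networks to a common total edge weight
#'
#' Multiplies every graph's weights by `commonTotal / w_i(E)` so that all
#' graphs carry the same total edge weight.  Conductance is invariant to this
#' scaling; only the aggregated inter-cluster edge cost is affected, which is
#' exactly why a common scale is needed before joint clustering.
#'
#' @param graphs list of [WeightedGraph-class] objects over an identical node
#'   set (same identifiers, same order), each with positive total weight.
#' @param commonTotal target total edge weight; defaults to the mean of the
#'   input totals, which keeps weight magnitudes familiar.
#' @param alphas optional per-graph conductance thresholds in (0,1).
#' @return A [GraphCollection-class].
#' @examples
#' g1 <- weightedGraph(matrix(c(0, 1, 1, 0), 2, 2,
#'                     dimnames = list(c("a", "b"), c("a", "b"))), "g1")
#' gc <- rescaleCollection(list(g1), commonTotal = 10)
#' totalWeight(graphs(gc)[[1]])
#' @export
rescaleCollection <- function(graphs, commonTotal = NULL, alphas = NA_real_) {
  if (is(graphs, "WeightedGraph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1L)
  nds <- lapply(graphs, nodes)
  for (i in seq_along(graphs)[-1L]) {
    if (!identical(nds[[i]], nds[[1L]])) {
      diff <- union(setdiff(nds[[i]], nds[[1L]]), setdiff(nds[[1L]], nds[[i]]))
      if (length(diff))
        stop("graphs disagree on the node universe; symmetric difference: ",
             paste(utils::head(diff, 10L), collapse = ", "), call. = FALSE)
      stop("graphs must list nodes in the same order", call. = FALSE)
    }
  }
  tot <- vapply(graphs, totalWeight, 0)
  if (any(tot <= 0))
    stop("graph(s) with zero total edge weight: ",
         paste(vapply(graphs[tot <= 0], graphName, ""), collapse = ", "),
         call. = FALSE)
  if (is.null(commonTotal)) commonTotal <- mean(tot)
  scaled <- mapply(function(g, f) {
    g@weights <- g@weights * f
    g
  }, graphs, commonTotal / tot, SIMPLIFY = FALSE)
  new("GraphCollection", graphs = scaled, commonTotal = commonTotal,
      alphas = as.numeric(alphas))
}

#' Read a GMT gene-set file
#'
#' Standard GMT format: one set per line, tab-separated fields
#' `name`, `description`, then the member genes.  Duplicate genes within a
#' set collapse; a line with fewer than three fields is a format error.
#'
#' @param path file path.
#' @param className label for the reference class (defaults to the file name).
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path, className = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file '", path, "' is empty", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " of '", path,
         "' has fewer than 3 fields", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  empty <- which(lengths(sets) == 0L)
  if (length(empty))
    stop("GMT line ", empty[1L], " of '", path, "' has an empty gene list",
         call. = FALSE)
  new("GeneSetCollection", className = className, sets = sets)
}

#' Construct a gene-set collection in code
#'
#' @param sets named list of character vectors.
#' @param className label for the reference class.
#' @return A [GeneSetCollection-class].
#' @export
geneSetCollection <- function(sets, className = "sets") {
  new("GeneSetCollection", className = className,
      sets = lapply(sets, function(s) unique(as.character(s))))
}
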