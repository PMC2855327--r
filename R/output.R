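# Writers for the cluster/tree result formats.

#' Write clusters as TSV with a JSON score sidecar
#'
#' The TSV has columns `cluster_rank` and `gene`; the JSON sidecar records,
#' per cluster, the per-graph modularity and the min-modularity score.
#'
#' @param partition a [Partition-class].
#' @param path output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
writeClusters <- function(partition, path) {
  cl <- partition@clusters
  df <- data.frame(cluster_rank = rep(seq_along(cl), lengths(cl)),
                   gene = unlist(cl, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- lapply(seq_along(cl), function(i) {
    rec <- list(rank = i, size = length(cl[[i]]))
    if (length(partition@minModularity)) {
      rec$modularity <- as.list(partition@perGraphModularity[i, ])
      rec$min_modularity <- partition@minModularity[i]
    }
    rec
  })
  jsonlite::write_json(side, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.treeToList <- function(node) {
  out <- list(size = length(node$set))
  if (is.null(node$left)) {
    out$genes <- node$set
  } else {
    cut <- node$cut
    out$cut <- list(source = cut@source,
                    scale = if (is.na(cut@scale)) "basic" else cut@scale,
                    conductances = as.list(cut@conductances))
    out$children <- list(.treeToList(node$left), .treeToList(node$right))
  }
  out
}

#' Write a clustering tree as nested JSON
#'
#' Internal nodes record the chosen cut (source graph, scale, per-graph
#' conductances); leaves record their gene sets.
#'
#' @param tree a [ClusteringTree-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeTree <- function(tree, path) {
  jsonlite::write_json(.treeToList(tree@root), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
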