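# Hypergeometric cluster-vs-gene-set enrichment with Bonferroni control,
# sensitivity/specificity summaries, cluster recovery, guilt-by-association
# function prediction and correlation support.

#' Hypergeometric enrichment of a cluster against a gene-set collection
#'
#' Upper-tail hypergeometric test of the overlap between the cluster and each
#' reference set, both restricted to the analysis universe (sets that become
#' empty after restriction are dropped).  Bonferroni correction multiplies
#' each raw p-value by the number of sets actually tested in the class; a
#' record is significant when the corrected p-value is strictly below
#' `cutoff` (default 0.005).
#'
#' @param cluster character vector of genes, a subset of `universe`.
#' @param sets a [GeneSetCollection-class].
#' @param universe character vector, the analysis universe (normally the
#'   common node set of the graph collection).
#' @param cutoff significance cutoff on the Bonferroni-corrected p (0.005).
#' @return `data.frame` with one row per tested set: `set_name`, `overlap`,
#'   `cluster_size`, `set_size`, `universe_size`, `p_raw`, `p_bonferroni`,
#'   `significant`.
#' @export
hypergeomEnrich <- function(cluster, sets, universe, cutoff = 0.005) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  cluster <- intersect(cluster, universe)
  ss <- lapply(sets@sets, intersect, universe)
  ss <- ss[lengths(ss) > 0L]
  if (!length(ss))
    return(data.frame(set_name = character(), overlap = integer(),
                      cluster_size = integer(), set_size = integer(),
                      universe_size = integer(), p_raw = numeric(),
                      p_bonferroni = numeric(), significant = logical()))
  U <- length(universe)
  n <- length(cluster)
  ov <- vapply(ss, function(s) length(intersect(s, cluster)), 0L)
  K <- lengths(ss)
  p <- phyper(ov - 1L, K, U - K, n, lower.tail = FALSE)
  pb <- pmin(1, p * length(ss))
  data.frame(set_name = names(ss), overlap = ov, cluster_size = n,
             set_size = unname(K), universe_size = U, p_raw = unname(p),
             p_bonferroni = unname(pb), significant = unname(pb < cutoff),
             row.names = NULL)
}

.reportable <- function(partition, minClusterSize) {
  cl <- if (is(partition, "Partition")) partition@clusters else partition
  cl[lengths(cl) >= minClusterSize]
}

#' Sensitivity and specificity of a clustering against reference classes
#'
#' For each reference class: sensitivity is the percentage of its reference
#' sets significantly enriched for the genes of some reported cluster, and
#' specificity the percentage of reported clusters significantly enriched for
#' some reference set, both at the Bonferroni-corrected cutoff.  Clusters
#' below `minClusterSize` genes are excluded from reporting.  Coverage (genes
#' in reported clusters) and the mean and sd of reported cluster sizes are
#' returned alongside.
#'
#' @param partition a [Partition-class].
#' @param classes list of [GeneSetCollection-class] objects (one per class);
#'   a single collection is accepted.
#' @param universe analysis universe.
#' @param minClusterSize minimum reported cluster size (default 10).
#' @param cutoff Bonferroni-corrected significance cutoff (default 0.005).
#' @return `data.frame` with one row per class: `class`, `n_sets`,
#'   `sensitivity`, `specificity` (percentages), `coverage`,
#'   `mean_cluster_size`, `sd_cluster_size`, `n_clusters`.
#' @export
sensitivitySpecificity <- function(partition, classes, universe,
                                   minClusterSize = 10L, cutoff = 0.005) {
  if (is(classes, "GeneSetCollection")) classes <- list(classes)
  cl <- .reportable(partition, minClusterSize)
  if (!length(cl)) stop("no reportable clusters of size >= ", minClusterSize,
                        call. = FALSE)
  out <- lapply(classes, function(cls) {
    enr <- lapply(cl, hypergeomEnrich, sets = cls, universe = universe,
                  cutoff = cutoff)
    allSets <- unique(unlist(lapply(enr, function(e) e$set_name)))
    hitSets <- unique(unlist(lapply(enr, function(e) e$set_name[e$significant])))
    clustHit <- vapply(enr, function(e) any(e$significant), TRUE)
    data.frame(class = cls@className, n_sets = length(allSets),
               sensitivity = 100 * length(hitSets) / max(1L, length(allSets)),
               specificity = 100 * mean(clustHit),
               coverage = length(unique(unlist(cl))),
               mean_cluster_size = mean(lengths(cl)),
               sd_cluster_size = sd(lengths(cl)),
               n_clusters = length(cl))
  })
  do.call(rbind, out)
}

#' Is a reference cluster recovered by a clustering?
#'
#' A reference cluster is recovered when it is significantly enriched for the
#' genes of some reported cluster of the partition (hypergeometric test,
#' Bonferroni-corrected over the number of reported clusters tested, cutoff
#' 0.005) — the same rule as reference-set enrichment with the roles of the
#' clusters as the sets.
#'
#' @param referenceCluster character vector of genes.
#' @param partition a [Partition-class].
#' @param universe analysis universe.
#' @param minClusterSize minimum reported cluster size (default 10).
#' @param cutoff Bonferroni-corrected significance cutoff (default 0.005).
#' @return Logical.
#' @export
recovered <- function(referenceCluster, partition, universe,
                      minClusterSize = 10L, cutoff = 0.005) {
  cl <- .reportable(partition, minClusterSize)
  if (!length(cl)) return(FALSE)
  names(cl) <- sprintf("cluster_%03d", seq_along(cl))
  enr <- hypergeomEnrich(referenceCluster,
                         geneSetCollection(cl, "detected clusters"),
                         universe, cutoff = cutoff)
  any(enr$significant)
}

#' Guilt-by-association function prediction for uncharacterized genes
#'
#' Annotates every uncharacterized gene belonging to a reported cluster with
#' at least one significant enrichment to the reference set for which its
#' cluster is most significantly enriched (smallest corrected p; ties break
#' to the lexicographically smallest set name).  Genes in unenriched clusters
#' or outside every reported cluster receive no prediction.
#'
#' @param partition a [Partition-class].
#' @param goSets a [GeneSetCollection-class] (typically GO biological
#'   process sets).
#' @param uncharacterized character vector of genes lacking annotation.
#' @param universe analysis universe.
#' @param minClusterSize minimum reported cluster size (default 10).
#' @param cutoff Bonferroni-corrected significance cutoff (default 0.005).
#' @return Named character vector mapping gene -> predicted set name.
#' @export
predictFunction <- function(partition, goSets, uncharacterized, universe,
                            minClusterSize = 10L, cutoff = 0.005) {
  cl <- .reportable(partition, minClusterSize)
  out <- character()
  for (C in cl) {
    enr <- hypergeomEnrich(C, goSets, universe, cutoff = cutoff)
    enr <- enr[enr$significant, , drop = FALSE]
    if (!nrow(enr)) next
    enr <- enr[order(enr$p_bonferroni, enr$set_name), , drop = FALSE]
    targets <- intersect(C, uncharacterized)
    if (length(targets))
      out[targets] <- enr$set_name[1L]
  }
  out
}

#' Correlation support of a gene within its cluster
#'
#' Two-sided Pearson correlation test of the gene's expression profile
#' against each other cluster member; a member supports the gene when the
#' test p-value is below `alpha` divided by the cluster size (Bonferroni).
#'
#' @param gene gene identifier.
#' @param cluster character vector, the cluster containing `gene`.
#' @param expr expression matrix (genes x samples, >= 3 samples) covering the
#'   gene and the cluster members.
#' @param alpha nominal level before correction (default 0.05).
#' @return List with `count` (supporting members), `fraction` (of the other
#'   members), and `threshold` (the corrected per-test level used).
#' @export
correlationSupport <- function(gene, cluster, expr, alpha = 0.05) {
  if (ncol(expr) < 3L) stop("at least 3 samples required", call. = FALSE)
  need <- union(gene, cluster)
  missing <- setdiff(need, rownames(expr))
  if (length(missing))
    stop("no expression profile for: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  others <- setdiff(cluster, gene)
  thr <- alpha / length(cluster)
  x <- expr[gene, ]
  pv <- vapply(others, function(m) cor.test(x, expr[m, ])$p.value, 0)
  list(count = sum(pv < thr), fraction = mean(pv < thr), threshold = thr)
}
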