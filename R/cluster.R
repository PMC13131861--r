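#' Correlation dissimilarity: distance = 1 - |r|
#'
#' Converts a region correlation matrix into the dissimilarity used for
#' hierarchical clustering of co-activity: strongly positive and strongly
#' negative correlations are both short distances (co-regulated activity),
#' while uncorrelated regions sit at the maximum distance of 1. Regions with
#' any undefined pairwise correlation are dropped first (and reported).
#'
#' @param corr a [region_correlations()] result.
#' @return square numeric matrix `1 - |r|` with zero diagonal; dropped region
#'   names are attached as attribute `dropped_regions`.
#' @export
to_dissimilarity <- function(corr) {
  stopifnot(inherits(corr, "group_corr"))
  r <- corr$r
  off_na <- is.na(r)
  diag(off_na) <- FALSE
  keep <- !apply(off_na, 1L, any)
  if (!any(keep)) stop("no region has a fully defined correlation profile")
  r <- r[keep, keep, drop = FALSE]
  d <- 1 - abs(r)
  diag(d) <- 0
  attr(d, "dropped_regions") <- rownames(corr$r)[!keep]
  d
}

#' UPGMA hierarchical clustering
#'
#' Agglomerative clustering with average linkage (unweighted pair group method
#' with arithmetic mean): at each step the two clusters with the smallest mean
#' inter-cluster dissimilarity are merged. Merge heights are monotone
#' non-decreasing for this linkage.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal (e.g.
#'   from [to_dissimilarity()]).
#' @return an object of class `hclust`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE))) {
    stop("dissimilarity matrix must be symmetric")
  }
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' @param dend an `hclust` tree from [upgma()].
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return named integer cluster assignment per region.
#' @export
cut_clusters <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1 || k > n) stop("k out of range")
  stats::cutree(dend, k = k)
}

#' Elbow curve of total within-cluster dissimilarity
#'
#' For each k from 1 to `k_max`, cuts the tree into k clusters and sums all
#' within-cluster pairwise dissimilarities. The curve is non-increasing in k,
#' equals the total pairwise dissimilarity at k = 1 and 0 at k = n. An
#' advisory elbow (the k maximizing the second difference of the curve) is
#' attached; the final choice of k is left to the analyst, as the elbow
#' heuristic is a visual one.
#'
#' @param dend an `hclust` tree.
#' @param d the dissimilarity matrix the tree was built from.
#' @param k_max largest k to evaluate (default: number of regions).
#' @return data.frame (`k`, `total_within`) with attribute `elbow_k`.
#' @export
elbow_curve <- function(dend, d, k_max = nrow(as.matrix(d))) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k_max > n) stop("k_max must be <= number of regions")
  total <- vapply(seq_len(k_max), function(k) {
    asgn <- stats::cutree(dend, k = k)
    sum(vapply(split(seq_along(asgn), asgn), function(mem) {
      sum(d[mem, mem, drop = FALSE]) / 2
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(k = seq_len(k_max), total_within = total)
  if (k_max >= 3) {
    d2 <- total[1:(k_max - 2)] - 2 * total[2:(k_max - 1)] + total[3:k_max]
    attr(out, "elbow_k") <- which.max(d2) + 1L
  }
  out
}

#' Export a dendrogram as Newick
#'
#' Writes the UPGMA tree in Newick format with branch lengths equal to
#' merge-height differences.
#'
#' @param dend an `hclust` tree.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}
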