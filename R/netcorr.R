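#' Per-group region co-activation correlation matrix
#'
#' Pairwise-complete Pearson correlations between all region pairs within one
#' group, with asymptotic two-sided p-values from the one-sample t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom, where
#' `n` is the number of subjects with data on both regions. Pairs with fewer
#' than `min_n` complete observations are marked undefined (NA).
#'
#' @param table region activity table (`subject_id`, `group`, region columns,
#'   possibly NA).
#' @param group group label to analyze.
#' @param min_n minimum complete pairs per correlation (default 4).
#' @return object of class `group_corr`: list with `r`, `p`, `n` (square
#'   matrices over regions) and `group`.
#' @export
region_correlations <- function(table, group, min_n = 4) {
  if (!group %in% table$group) stop("group not found: ", group)
  m <- feature_matrix(table[table$group == group, , drop = FALSE])
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(m))
  too_few <- n < min_n
  r[too_few] <- NA_real_
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(r) <- 1
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, group = group), class = "group_corr")
}

#' Significance mask at a given alpha
#'
#' @param corr a [region_correlations()] result.
#' @param alpha significance level in (0, 1]; comparison is strict
#'   (`p < alpha`).
#' @return symmetric logical matrix; undefined pairs and the diagonal are
#'   FALSE.
#' @export
significance_mask <- function(corr, alpha) {
  stopifnot(inherits(corr, "group_corr"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  mask <- corr$p < alpha
  mask[is.na(mask)] <- FALSE
  diag(mask) <- FALSE
  mask
}

# internal constructor for thresholded networks
corr_network <- function(nodes, edges, provenance) {
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "corr_network")
}

#' Joined proportionally-thresholded networks across groups
#'
#' Builds one network per group over a shared node set (regions whose
#' correlations are defined in every group), keeping in each group the edges
#' with the smallest p-values up to the requested edge density (fraction of
#' all possible node pairs). Ties are broken by larger |r|, then by the
#' lexicographic pair label, so the edge set is deterministic.
#'
#' @param corrs named list of [region_correlations()] results (>= 2 groups).
#' @param edge_density fraction of possible edges to retain, in (0, 1].
#' @return named list of `corr_network` objects (fields: `nodes`, `edges`
#'   data.frame with `region_a`, `region_b`, `r`, `p`, and `provenance`
#'   recording the rule and achieved density).
#' @export
joined_network <- function(corrs, edge_density = 0.015) {
  if (length(corrs) < 2) stop("need at least 2 groups")
  if (edge_density <= 0 || edge_density > 1) stop("edge_density must be in (0, 1]")
  defined_in <- lapply(corrs, function(cc) {
    p_off <- cc$p
    diag(p_off) <- 0
    rownames(cc$r)[apply(is.finite(p_off), 1L, all)]
  })
  nodes <- sort(Reduce(intersect, defined_in))
  n <- length(nodes)
  if (n < 2) stop("fewer than 2 regions have defined correlations in all groups")
  n_pairs <- n * (n - 1) / 2
  m <- round(edge_density * n_pairs)
  if (m < 1) stop("requested edge density yields zero edges")
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lapply(corrs, function(cc) {
    r <- cc$r[nodes, nodes]
    p <- cc$p[nodes, nodes]
    edges <- data.frame(
      region_a = nodes[ut[, 1]], region_b = nodes[ut[, 2]],
      r = r[ut], p = p[ut], stringsAsFactors = FALSE
    )
    ord <- order(edges$p, -abs(edges$r), edges$region_a, edges$region_b)
    edges <- edges[ord[seq_len(m)], , drop = FALSE]
    rownames(edges) <- NULL
    corr_network(nodes, edges, list(
      rule = "proportional threshold by p-value",
      requested_density = edge_density,
      achieved_density = m / n_pairs,
      n_edges = m, group = cc$group
    ))
  })
}

#' Global topology metrics of an unweighted network
#'
#' Treats the network as simple, undirected and unweighted and returns:
#' mean degree (2E/N); global efficiency, the mean over ordered node pairs of
#' the inverse shortest-path length with disconnected pairs contributing 0;
#' mean local clustering coefficient (triangles over possible, 0 for nodes of
#' degree < 2); and mean betweenness centrality normalized by
#' `(N - 1)(N - 2) / 2` node pairs.
#'
#' @param net a `corr_network` (from [joined_network()]) or any list with
#'   `nodes` and an `edges` data.frame whose first two columns name the
#'   endpoints.
#' @return named numeric vector: `mean_degree`, `mean_efficiency`,
#'   `mean_clustering`, `mean_betweenness`.
#' @export
topology_metrics <- function(net) {
  nodes <- net$nodes
  if (length(nodes) == 0) stop("empty node set")
  g <- igraph::graph_from_data_frame(net$edges[, 1:2, drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  nv <- length(nodes)
  mean_degree <- mean(igraph::degree(g))
  eff <- if (nv < 2 || igraph::ecount(g) == 0) 0 else
    igraph::global_efficiency(g)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[is.na(cl)] <- 0
  btw <- if (nv < 3 || igraph::ecount(g) == 0) rep(0, nv) else
    igraph::betweenness(g, normalized = TRUE)
  c(mean_degree = mean_degree, mean_efficiency = eff,
    mean_clustering = mean(cl), mean_betweenness = mean(btw))
}

#' Default threshold grid for topology sweeps
#'
#' @param n number of grid points.
#' @return `n` log-spaced alpha values from 0.001 to 1.
#' @export
alpha_grid <- function(n = 40) exp(seq(log(0.001), log(1), length.out = n))

#' Topology metrics across an alpha-threshold sweep
#'
#' At each alpha, the network keeps every region pair with `p < alpha`
#' (strict); nodes are all regions of the correlation matrix, so edge sets are
#' nested along the grid and mean degree is non-decreasing.
#'
#' @param corr a [region_correlations()] result.
#' @param alphas ascending threshold grid in (0, 1]; default [alpha_grid()].
#' @return data.frame: `alpha`, `mean_degree`, `mean_efficiency`,
#'   `mean_clustering`, `mean_betweenness`.
#' @export
threshold_sweep <- function(corr, alphas = alpha_grid()) {
  stopifnot(inherits(corr, "group_corr"))
  if (is.unsorted(alphas)) stop("alphas must be sorted ascending")
  nodes <- rownames(corr$r)
  ut <- which(upper.tri(corr$p), arr.ind = TRUE)
  p_ut <- corr$p[ut]
  ok <- is.finite(p_ut)
  rows <- lapply(alphas, function(a) {
    keep <- ok & p_ut < a
    net <- list(nodes = nodes,
                edges = data.frame(region_a = nodes[ut[keep, 1]],
                                   region_b = nodes[ut[keep, 2]],
                                   stringsAsFactors = FALSE))
    c(alpha = a, topology_metrics(net))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Distribution of absolute correlations
#'
#' Upper-triangle |r| values of a group correlation matrix, optionally
#' restricted to a named region subset (e.g. a sensorimotor block or one
#' cluster from [upgma()]). Undefined pairs are omitted.
#'
#' @param corr a [region_correlations()] result.
#' @param region_subset optional character vector of region names.
#' @return numeric vector of |r| values.
#' @export
abs_r_distribution <- function(corr, region_subset = NULL) {
  stopifnot(inherits(corr, "group_corr"))
  r <- corr$r
  if (!is.null(region_subset)) {
    unknown <- setdiff(region_subset, rownames(r))
    if (length(unknown)) stop("unknown regions: ", paste(unknown, collapse = ", "))
    r <- r[region_subset, region_subset, drop = FALSE]
  }
  vals <- abs(r[upper.tri(r)])
  vals[!is.na(vals)]
}
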