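# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson correlation straight from the definition
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# O(n^3) average-linkage agglomeration returning the cophenetic matrix
# (height at which each leaf pair first shares a cluster)
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- best[1]
      coph[b, a] <- best[1]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# graph metrics from an adjacency matrix, via Floyd-Warshall shortest paths,
# direct triangle counting, and exhaustive shortest-path enumeration for
# betweenness
oracle_graph_metrics <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  dist[adj == 1] <- 1
  diag(dist) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        alt <- dist[i, k] + dist[k, j]
        if (alt < dist[i, j]) dist[i, j] <- alt
      }
    }
  }
  # efficiency
  inv <- 1 / dist
  diag(inv) <- 0
  inv[is.infinite(dist)] <- 0
  efficiency <- if (n < 2) 0 else sum(inv) / (n * (n - 1))
  # degree and local clustering
  deg <- rowSums(adj)
  clust <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    sum(adj[nb, nb]) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  # betweenness by exhaustive enumeration of shortest paths
  paths_through <- numeric(n)
  enumerate <- function(cur, target, dleft, visited) {
    if (cur == target) return(list(visited))
    if (dleft == 0) return(list())
    out <- list()
    for (nxt in which(adj[cur, ] == 1)) {
      if (dist[nxt, target] == dleft - 1) {
        out <- c(out, enumerate(nxt, target, dleft - 1, c(visited, nxt)))
      }
    }
    out
  }
  btw <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (!is.finite(dist[s, t])) next
        allp <- enumerate(s, t, dist[s, t], s)
        inner <- unlist(lapply(allp, function(p) p[-c(1, length(p))]))
        if (length(inner)) {
          tb <- table(inner)
          idx <- as.integer(names(tb))
          btw[idx] <- btw[idx] + as.numeric(tb) / length(allp)
        }
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }
  c(mean_degree = mean(deg), mean_efficiency = efficiency,
    mean_clustering = mean(clust), mean_betweenness = mean(btw))
}

# adjacency -> the minimal network shape topology_metrics() accepts
adj_to_net <- function(adj) {
  n <- nrow(adj)
  nodes <- sprintf("n%02d", seq_len(n))
  ut <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  list(nodes = nodes,
       edges = data.frame(region_a = nodes[ut[, 1]],
                          region_b = nodes[ut[, 2]],
                          stringsAsFactors = FALSE))
}

# ROC by exhaustive threshold enumeration
oracle_roc_auc <- function(scores, labels) {
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(th) mean(scores[labels] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(scores[!labels] >= th), numeric(1))
  ord <- order(fpr, tpr)
  fpr <- c(0, fpr[ord], 1)
  tpr <- c(0, tpr[ord], 1)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# partition equality up to label renaming: the label pairs (a_i, b_i) must
# form a bijection between the two label sets
same_partition <- function(a, b) {
  pairs <- unique(paste(a, b))
  length(pairs) == length(unique(a)) && length(pairs) == length(unique(b))
}
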