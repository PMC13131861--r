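# shared internal helpers

# Deterministic child-seed derivation: one user-facing seed fans out to
# independent per-generator streams via a fixed MINSTD-style map. Offsets are
# arbitrary but frozen; all arithmetic stays exact in doubles (< 2^53).
child_seed <- function(seed, stream) {
  offsets <- c(
    brain_behavior = 101, labeled_features = 211, activity = 307,
    hypnogram = 401, eeg = 503, trajectory = 601,
    permutation = 701, bootstrap = 809, scores = 907,
    crossval = 1009, shuffle = 1103
  )
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  as.integer(((as.double(seed) %% 2147483647) * 48271 + offsets[[stream]]) %%
               2147483647)
}

# column-standardize a numeric matrix (mean 0, unit sd with ddof = 1);
# errors name the offending column so upstream tables are easy to fix
standardize_cols <- function(m, what = "column") {
  n <- nrow(m)
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu, "-")
  s <- sqrt(colSums(xc^2) / (n - 1))
  if (any(s == 0 | !is.finite(s))) {
    bad <- colnames(m)[which(s == 0 | !is.finite(s))[1L]]
    stop("zero-variance ", what, ": ", bad)
  }
  sweep(xc, 2L, s, "/")
}

# numeric feature block of a table with subject_id/group/class id columns
feature_matrix <- function(tab) {
  keep <- setdiff(names(tab), c("subject_id", "group", "class"))
  m <- as.matrix(tab[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$subject_id
  m
}

check_aligned_subjects <- function(x, y) {
  if (!identical(as.character(x$subject_id), as.character(y$subject_id))) {
    stop("behavior and brain tables must contain the same subjects in the same order")
  }
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}
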