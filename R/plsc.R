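#' Filter and impute a region activity table
#'
#' Regions with more than `max_missing_per_group` missing values in any group
#' are dropped; remaining missing entries are replaced by the median of the
#' observed values of that region within the subject's own group (missingness
#' is treated as missing-at-random). The result contains no missing values.
#'
#' @param table data.frame with `subject_id`, `group` and region columns.
#' @param max_missing_per_group maximum tolerated missing values per region
#'   within a group before the region is removed (default 2).
#' @return the filtered, imputed table; dropped region names are attached as
#'   attribute `dropped_regions`.
#' @export
impute_and_filter <- function(table, max_missing_per_group = 2) {
  groups <- unique(table$group)
  if (length(groups) == 0) stop("table has no groups")
  sizes <- table(table$group)
  if (any(sizes <= max_missing_per_group)) {
    stop("every group must be larger than max_missing_per_group")
  }
  regions <- setdiff(names(table), c("subject_id", "group"))
  miss_by_group <- vapply(regions, function(rg) {
    max(tapply(is.na(table[[rg]]), table$group, sum))
  }, numeric(1))
  dropped <- regions[miss_by_group > max_missing_per_group]
  kept <- setdiff(regions, dropped)
  out <- table[, c("subject_id", "group", kept), drop = FALSE]
  for (rg in kept) {
    if (!anyNA(out[[rg]])) next
    med <- tapply(out[[rg]], out$group, stats::median, na.rm = TRUE)
    na_idx <- which(is.na(out[[rg]]))
    out[[rg]][na_idx] <- med[out$group[na_idx]]
  }
  attr(out, "dropped_regions") <- dropped
  out
}

#' Cross-block correlation matrix
#'
#' Pearson correlation of every behavioral feature with every brain region
#' across subjects: the two blocks are column-standardized (centered, scaled)
#' and their cross-product divided by n - 1, which is the matrix that is then
#' decomposed by [plsc_decompose()].
#'
#' @param X behavior table (`subject_id`, `group`, feature columns), complete.
#' @param Y region activity table aligned to `X` subject-for-subject,
#'   complete (run [impute_and_filter()] first).
#' @return behaviors x regions correlation matrix of class `cross_corr` with
#'   attribute `n_subjects`.
#' @export
cross_correlation <- function(X, Y) {
  check_aligned_subjects(X, Y)
  mx <- feature_matrix(X)
  my <- feature_matrix(Y)
  if (anyNA(mx) || anyNA(my)) stop("blocks must be complete; impute first")
  zx <- standardize_cols(mx, "behavior column")
  zy <- standardize_cols(my, "region column")
  R <- crossprod(zx, zy) / (nrow(zx) - 1)
  attr(R, "n_subjects") <- nrow(zx)
  class(R) <- c("cross_corr", class(R))
  R
}

#' Singular value decomposition of the cross-block correlation
#'
#' Decomposes `R = U diag(d) V'` into pairs of latent variables. Behavior
#' saliences (columns of U) and brain saliences (columns of V) are the weights
#' of the original features on each latent variable; `d[i]^2 / sum(d^2)` is
#' the fraction of shared cross-block covariance ("inertia") captured by LV i.
#' The SVD sign indeterminacy is fixed deterministically: the
#' largest-magnitude element of each behavior-salience column is made
#' positive, and the paired brain column follows.
#'
#' @param R a [cross_correlation()] matrix (finite entries).
#' @return object of class `plsc_result`: `d` (singular values, descending),
#'   `u` (behavior saliences), `v` (brain saliences), `variance_explained`,
#'   `inertia` (= sum of squared singular values).
#' @export
plsc_decompose <- function(R) {
  if (!all(is.finite(R))) stop("cross-correlation matrix has non-finite entries")
  s <- svd(R)
  for (j in seq_along(s$d)) {
    i0 <- which.max(abs(s$u[, j]))
    if (s$u[i0, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  rownames(s$u) <- rownames(R)
  rownames(s$v) <- colnames(R)
  structure(list(
    d = s$d, u = s$u, v = s$v,
    variance_explained = s$d^2 / sum(s$d^2),
    inertia = sum(s$d^2),
    n_subjects = attr(R, "n_subjects")
  ), class = "plsc_result")
}

# internal: standardized blocks + observed decomposition, shared by the
# resampling routines
plsc_blocks <- function(X, Y) {
  check_aligned_subjects(X, Y)
  zx <- standardize_cols(feature_matrix(X), "behavior column")
  zy <- standardize_cols(feature_matrix(Y), "region column")
  list(zx = zx, zy = zy, n = nrow(zx))
}

#' Permutation test for latent-variable significance
#'
#' Subject rows of the brain block are permuted relative to the behavior
#' block; the cross-block correlation and its singular values are recomputed
#' for each permutation, giving a null distribution of covariance strength
#' per latent variable. The per-LV p-value uses the add-one estimator
#' `(count(null >= observed) + 1) / (n_perm + 1)`, so the smallest attainable
#' p at 10,000 permutations is about 1e-4. A latent variable is flagged
#' significant when its observed singular value exceeds the 95th percentile
#' of its permutation null. An omnibus test on the inertia (sum of squared
#' singular values) is computed the same way.
#'
#' @param X,Y aligned, complete behavior and brain tables.
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed integer seed.
#' @param percentile significance percentile of the null (default 0.95).
#' @return list: `perm_p` (per LV), `inertia_p`, `significant` (logical per
#'   LV), `null_q` (per-LV null percentile cutoffs), `observed_d`, `n_perm`.
#' @export
plsc_permutation <- function(X, Y, n_perm = 10000, seed = 1,
                             percentile = 0.95) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  b <- plsc_blocks(X, Y)
  if (b$n < 3) stop("too few subjects to permute")
  d_obs <- svd(crossprod(b$zx, b$zy) / (b$n - 1), nu = 0, nv = 0)$d
  k <- length(d_obs)
  set.seed(child_seed(seed, "permutation"))
  null_d <- matrix(0, n_perm, k)
  for (i in seq_len(n_perm)) {
    Rp <- crossprod(b$zx, b$zy[sample.int(b$n), , drop = FALSE]) / (b$n - 1)
    null_d[i, ] <- svd(Rp, nu = 0, nv = 0)$d
  }
  ge <- colSums(sweep(null_d, 2L, d_obs, ">="))
  perm_p <- (ge + 1) / (n_perm + 1)
  null_inertia <- rowSums(null_d^2)
  inertia_obs <- sum(d_obs^2)
  q <- apply(null_d, 2L, stats::quantile, probs = percentile, names = FALSE)
  list(
    perm_p = perm_p,
    inertia_p = (sum(null_inertia >= inertia_obs) + 1) / (n_perm + 1),
    significant = d_obs > q,
    null_q = q,
    observed_d = d_obs,
    n_perm = n_perm
  )
}

#' Bootstrap ratios for salience stability
#'
#' Subjects are resampled with replacement; each replicate's saliences are
#' sign-aligned per latent variable to the original solution (sign of the
#' combined dot product of the replicate's behavior and brain salience columns
#' with the originals) and the bootstrap ratio is the original salience
#' divided by the standard deviation (ddof = 1) of the aligned replicate
#' saliences. |BR| > 2 (strict) approximates a 95% confidence interval and is
#' returned as the stability flag. Replicates that produce a zero-variance
#' column are redrawn (counted, capped).
#'
#' @param X,Y aligned, complete behavior and brain tables.
#' @param n_boot number of bootstrap resamples (>= 100; default 10000).
#' @param seed integer seed.
#' @return list: `boot_ratio_behavior` and `boot_ratio_brain` (feature x LV
#'   matrices), `flag_behavior`/`flag_brain` (|BR| > 2), `n_redrawn`.
#' @export
plsc_bootstrap <- function(X, Y, n_boot = 10000, seed = 1) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  b <- plsc_blocks(X, Y)
  mx <- feature_matrix(X)
  my <- feature_matrix(Y)
  res <- plsc_decompose(cross_correlation(X, Y))
  k <- length(res$d)
  sum_u <- matrix(0, nrow(res$u), k); ss_u <- sum_u
  sum_v <- matrix(0, nrow(res$v), k); ss_v <- sum_v
  set.seed(child_seed(seed, "bootstrap"))
  n_redrawn <- 0L
  max_redraw <- 100L + 10L * n_boot
  done <- 0L
  while (done < n_boot) {
    idx <- sample.int(b$n, replace = TRUE)
    bx <- mx[idx, , drop = FALSE]
    by <- my[idx, , drop = FALSE]
    ok <- all(matrixStats_sd_ok(bx)) && all(matrixStats_sd_ok(by))
    if (!ok) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_redraw) stop("too many degenerate bootstrap samples")
      next
    }
    Rb <- crossprod(standardize_cols(bx), standardize_cols(by)) / (b$n - 1)
    sb <- svd(Rb)
    for (j in seq_len(k)) {
      sgn <- sum(sb$u[, j] * res$u[, j]) + sum(sb$v[, j] * res$v[, j])
      if (sgn < 0) {
        sb$u[, j] <- -sb$u[, j]
        sb$v[, j] <- -sb$v[, j]
      }
    }
    sum_u <- sum_u + sb$u[, seq_len(k), drop = FALSE]
    ss_u <- ss_u + sb$u[, seq_len(k), drop = FALSE]^2
    sum_v <- sum_v + sb$v[, seq_len(k), drop = FALSE]
    ss_v <- ss_v + sb$v[, seq_len(k), drop = FALSE]^2
    done <- done + 1L
  }
  sd_from_moments <- function(sm, ssq, n) {
    v <- (ssq - sm^2 / n) / (n - 1)
    sqrt(pmax(v, 0))
  }
  se_u <- sd_from_moments(sum_u, ss_u, n_boot)
  se_v <- sd_from_moments(sum_v, ss_v, n_boot)
  br_u <- res$u / se_u
  br_v <- res$v / se_v
  dimnames(br_u) <- dimnames(res$u)
  dimnames(br_v) <- dimnames(res$v)
  list(
    boot_ratio_behavior = br_u, boot_ratio_brain = br_v,
    flag_behavior = abs(br_u) > 2, flag_brain = abs(br_v) > 2,
    n_redrawn = n_redrawn
  )
}

# TRUE per column when the column has positive variance in a resample
matrixStats_sd_ok <- function(m) {
  rng_lo <- apply(m, 2L, min)
  rng_hi <- apply(m, 2L, max)
  rng_hi > rng_lo
}

#' Subject scores on a latent variable
#'
#' Projects the standardized behavior and brain blocks onto the chosen latent
#' variable's saliences, giving one score pair per subject, with per-group
#' mean and a percentile-bootstrap confidence interval for the mean (subjects
#' resampled within group).
#'
#' @param X,Y aligned, complete behavior and brain tables.
#' @param result a [plsc_decompose()] result.
#' @param lv latent-variable index.
#' @param n_boot bootstrap resamples for the group-mean CI.
#' @param conf confidence level (default 0.95, i.e. 2.5/97.5 percentiles).
#' @param seed integer seed.
#' @return list: `scores` (subject_id, group, behavior_score, brain_score)
#'   and `group_stats` (per-group means with CI bounds).
#' @export
latent_scores <- function(X, Y, result, lv = 1, n_boot = 2000, conf = 0.95,
                          seed = 1) {
  stopifnot(inherits(result, "plsc_result"))
  if (lv < 1 || lv > length(result$d)) stop("lv out of range")
  b <- plsc_blocks(X, Y)
  sx <- drop(b$zx %*% result$u[, lv])
  sy <- drop(b$zy %*% result$v[, lv])
  scores <- data.frame(subject_id = X$subject_id, group = X$group,
                       behavior_score = sx, brain_score = sy,
                       stringsAsFactors = FALSE)
  set.seed(child_seed(seed, "scores"))
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  stats_list <- lapply(split(scores, scores$group), function(gd) {
    ng <- nrow(gd)
    bm <- matrix(0, n_boot, 2)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(ng, replace = TRUE)
      bm[i, ] <- c(mean(gd$behavior_score[idx]), mean(gd$brain_score[idx]))
    }
    qx <- stats::quantile(bm[, 1], probs, names = FALSE)
    qy <- stats::quantile(bm[, 2], probs, names = FALSE)
    data.frame(group = gd$group[1],
               mean_behavior = mean(gd$behavior_score),
               behavior_lo = qx[1], behavior_hi = qx[2],
               mean_brain = mean(gd$brain_score),
               brain_lo = qy[1], brain_hi = qy[2],
               stringsAsFactors = FALSE)
  })
  list(scores = scores,
       group_stats = do.call(rbind, c(stats_list, make.row.names = FALSE)))
}

#' Behavioral PLSC in one call
#'
#' Convenience wrapper: imputes/filters the brain block, forms the
#' cross-block correlation, decomposes it, and runs the permutation and
#' bootstrap inference.
#'
#' @inheritParams plsc_permutation
#' @param n_boot bootstrap resamples.
#' @param max_missing_per_group see [impute_and_filter()].
#' @return list: `result` ([plsc_decompose()] output with `perm_p`,
#'   `inertia_p`, `significant` added), `bootstrap` ([plsc_bootstrap()]
#'   output), `Y_used` (the filtered, imputed brain table).
#' @export
plsc <- function(X, Y, n_perm = 10000, n_boot = 10000, seed = 1,
                 max_missing_per_group = 2) {
  Yf <- impute_and_filter(Y, max_missing_per_group)
  res <- plsc_decompose(cross_correlation(X, Yf))
  perm <- plsc_permutation(X, Yf, n_perm = n_perm, seed = seed)
  boot <- plsc_bootstrap(X, Yf, n_boot = n_boot, seed = seed)
  res$perm_p <- perm$perm_p
  res$inertia_p <- perm$inertia_p
  res$significant <- perm$significant
  list(result = res, bootstrap = boot, Y_used = Yf)
}
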