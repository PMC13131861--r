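make_tables <- function(n = 12, p_b = 4, p_r = 6, seed = 1, groups = "A") {
  set.seed(seed)
  n_g <- n / length(groups)
  X <- matrix(rnorm(n * p_b), n, p_b,
              dimnames = list(NULL, paste0("b", seq_len(p_b))))
  Y <- matrix(rnorm(n * p_r), n, p_r,
              dimnames = list(NULL, paste0("r", seq_len(p_r))))
  list(
    X = data.frame(subject_id = sprintf("s%02d", 1:n),
                   group = rep(groups, each = n_g), X),
    Y = data.frame(subject_id = sprintf("s%02d", 1:n),
                   group = rep(groups, each = n_g), Y)
  )
}

test_that("regions exceeding the per-group missingness cap are dropped", {
  tb <- make_tables(n = 12, groups = c("g1", "g2"))$Y
  tb$r1[1:3] <- NA      # 3 missing in g1: dropped at max 2
  tb$r2[1:2] <- NA      # 2 missing in g1: kept and imputed
  out <- impute_and_filter(tb, max_missing_per_group = 2)
  expect_false("r1" %in% names(out))
  expect_true("r2" %in% names(out))
  expect_false(anyNA(out))
  expect_identical(attr(out, "dropped_regions"), "r1")
})

test_that("imputation uses the group-wise median of observed values", {
  tb <- data.frame(subject_id = paste0("s", 1:8),
                   group = rep(c("g1", "g2"), each = 4),
                   r1 = c(1, 2, NA, 4, 10, 20, 30, 40))
  out <- impute_and_filter(tb)
  expect_equal(out$r1[3], 2)            # median of 1, 2, 4
  # a complete table passes through unchanged
  tb2 <- make_tables()$Y
  expect_equal(impute_and_filter(tb2)$r3, tb2$r3)
  # groups no larger than the cap are rejected
  expect_error(impute_and_filter(tb[c(1, 2, 5, 6), ]), "larger")
})

test_that("cross correlation matches the direct Pearson formula", {
  tb <- make_tables(n = 10, p_b = 3, p_r = 3, seed = 2)
  R <- cross_correlation(tb$X, tb$Y)
  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(R[i, j], oracle_pearson(tb$X[[i + 2]], tb$Y[[j + 2]]),
                   tolerance = 1e-12)
    }
  }
  # identical / negated columns hit the bounds
  tb$Y$r1 <- tb$X$b1
  tb$Y$r2 <- -tb$X$b2
  R <- cross_correlation(tb$X, tb$Y)
  expect_equal(unname(R["b1", "r1"]), 1, tolerance = 1e-12)
  expect_equal(unname(R["b2", "r2"]), -1, tolerance = 1e-12)
  # zero-variance columns are named in the error
  tb$Y$r3 <- 5
  expect_error(cross_correlation(tb$X, tb$Y), "r3")
})

test_that("decomposition satisfies the SVD identities", {
  R <- diag(c(3, 1))
  class(R) <- c("cross_corr", class(R))
  res <- plsc_decompose(R)
  expect_equal(res$d, c(3, 1))
  expect_equal(res$variance_explained, c(0.9, 0.1))

  tb <- make_tables(n = 15, p_b = 5, p_r = 8, seed = 3)
  res <- plsc_decompose(cross_correlation(tb$X, tb$Y))
  expect_equal(sum(res$variance_explained), 1, tolerance = 1e-12)
  expect_equal(crossprod(res$u), diag(ncol(res$u)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(res$v), diag(ncol(res$v)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$inertia, sum(res$d^2), tolerance = 1e-12)
})

test_that("a rank-1 matrix is recovered up to sign", {
  set.seed(4)
  u <- rnorm(5); u <- u / sqrt(sum(u^2))
  v <- rnorm(9); v <- v / sqrt(sum(v^2))
  R <- 2.5 * outer(u, v)
  res <- plsc_decompose(R)
  expect_equal(res$d[1], 2.5, tolerance = 1e-10)
  expect_lt(res$d[2], 1e-10)
  expect_gt(abs(sum(res$u[, 1] * u)), 1 - 1e-10)
  expect_gt(abs(sum(res$v[, 1] * v)), 1 - 1e-10)
})

test_that("permutation p-values behave as add-one estimators", {
  cfg <- synth_config(seed = 5, n_per_group = 30, groups = "A",
                      n_regions = 10, n_behaviors = 6, latent_strength = 4,
                      latent_rank = 1)
  dat <- gen_brain_behavior(cfg)
  perm <- plsc_permutation(dat$behavior, dat$activity, n_perm = 200, seed = 6)
  # strongly planted LV1 beats every permutation: p is the floor 1/(n+1)
  expect_equal(perm$perm_p[1], 1 / 201)
  expect_true(perm$significant[1])
  expect_true(all(perm$perm_p >= 1 / 201 & perm$perm_p <= 1))
  expect_error(plsc_permutation(dat$behavior, dat$activity, n_perm = 50),
               "n_perm")
})

test_that("permutation p-values are invariant to region relabeling", {
  tb <- make_tables(n = 14, p_b = 4, p_r = 6, seed = 7)
  p1 <- plsc_permutation(tb$X, tb$Y, n_perm = 150, seed = 8)$perm_p
  reord <- tb$Y[, c("subject_id", "group", sample(paste0("r", 1:6)))]
  p2 <- plsc_permutation(tb$X, reord, n_perm = 150, seed = 8)$perm_p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("bootstrap ratios flag planted loadings and spare null features", {
  cfg <- synth_config(seed = 9, n_per_group = 200, groups = "A",
                      n_regions = 12, n_behaviors = 8, latent_rank = 1,
                      latent_strength = 1.5, behavior_idx = 1:3,
                      region_idx = 1:4)
  dat <- gen_brain_behavior(cfg)
  boot <- plsc_bootstrap(dat$behavior, dat$activity, n_boot = 400, seed = 10)
  br_b <- boot$boot_ratio_behavior[, 1]
  expect_true(all(abs(br_b[1:3]) > 2))
  expect_true(all(abs(boot$boot_ratio_brain[1:4, 1]) > 2))
  # flags use strict inequality on |BR| = 2
  expect_identical(boot$flag_behavior, abs(boot$boot_ratio_behavior) > 2)
  # most null behavior features stay inside the threshold
  expect_gt(mean(abs(br_b[4:8]) < 2), 0.5)
})

test_that("latent scores are standardized projections with valid group CIs", {
  # two groups with separated latent factors
  set.seed(11)
  n_g <- 20
  z <- c(rnorm(n_g, 3), rnorm(n_g, -3))
  u <- c(1, 1) / sqrt(2); v <- c(1, -1, 1) / sqrt(3)
  X <- outer(z, u) + 0.3 * matrix(rnorm(2 * n_g * 2), 2 * n_g, 2)
  Y <- outer(z, v) + 0.3 * matrix(rnorm(2 * n_g * 3), 2 * n_g, 3)
  colnames(X) <- c("b1", "b2"); colnames(Y) <- c("r1", "r2", "r3")
  Xt <- data.frame(subject_id = sprintf("s%02d", 1:(2 * n_g)),
                   group = rep(c("hi", "lo"), each = n_g), X)
  Yt <- data.frame(subject_id = Xt$subject_id, group = Xt$group, Y)
  res <- plsc_decompose(cross_correlation(Xt, Yt))
  ls1 <- latent_scores(Xt, Yt, res, lv = 1, n_boot = 500, seed = 12)
  gs <- ls1$group_stats
  expect_true(all(gs$behavior_lo <= gs$mean_behavior &
                    gs$mean_behavior <= gs$behavior_hi))
  # planted separation: group CIs do not overlap on either side
  hi <- gs[gs$group == "hi", ]; lo <- gs[gs$group == "lo", ]
  expect_true(hi$behavior_lo > lo$behavior_hi || lo$behavior_lo > hi$behavior_hi)
  expect_true(hi$brain_lo > lo$brain_hi || lo$brain_lo > hi$brain_hi)
  # scale invariance: doubling brain columns leaves scores unchanged
  Yt2 <- Yt
  for (cc in c("r1", "r2", "r3")) Yt2[[cc]] <- 2 * Yt2[[cc]]
  ls2 <- latent_scores(Xt, Yt2, res, lv = 1, n_boot = 10, seed = 12)
  expect_equal(ls1$scores$brain_score, ls2$scores$brain_score,
               tolerance = 1e-12)
  expect_error(latent_scores(Xt, Yt, res, lv = 10), "lv")
})
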