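make_activity <- function(n = 10, p = 6, seed = 1, group = "A",
                          missing = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("r", seq_len(p))))
  if (missing > 0) m[sample(length(m), missing)] <- NA
  data.frame(subject_id = sprintf("s%02d", seq_len(n)), group = group, m)
}

test_that("region correlations match cor.test r and p", {
  tb <- make_activity(n = 9, p = 5, seed = 2)
  gc <- region_correlations(tb, "A")
  expect_true(isSymmetric(gc$r))
  expect_true(all(diag(gc$r) == 1))
  m <- as.matrix(tb[, -(1:2)])
  for (i in 1:4) {
    for (j in (i + 1):5) {
      ct <- cor.test(m[, i], m[, j])
      expect_equal(gc$r[i, j], unname(ct$estimate), tolerance = 1e-12)
      expect_equal(gc$p[i, j], ct$p.value, tolerance = 1e-10)
    }
  }
  expect_error(region_correlations(tb, "missing-group"), "group")
})

test_that("pairs with too few complete observations are undefined", {
  tb <- make_activity(n = 6, p = 4, seed = 3)
  tb$r1[1:3] <- NA       # only 3 complete pairs with every other region
  gc <- region_correlations(tb, "A")
  expect_true(all(is.na(gc$r[1, 2:4])))
  expect_true(all(is.na(gc$p[1, 2:4])))
  expect_false(anyNA(gc$r[2:4, 2:4]))
})

test_that("significance mask is strict, symmetric, and alpha-monotone", {
  tb <- make_activity(n = 12, p = 8, seed = 4)
  gc <- region_correlations(tb, "A")
  m1 <- significance_mask(gc, 1)
  expect_true(all(m1[upper.tri(m1)]))       # p < 1 for continuous data
  expect_false(any(diag(m1)))
  m005 <- significance_mask(gc, 0.005)
  expect_true(all(m005 == t(m005)))
  expect_true(all(m005[upper.tri(m005)] == (gc$p < 0.005)[upper.tri(m005)]))
  # below the attainable floor at this n, nothing passes
  floor_p <- min(gc$p[upper.tri(gc$p)])
  expect_false(any(significance_mask(gc, floor_p / 2)))
  expect_error(significance_mask(gc, 0), "alpha")
})

test_that("mask density grows with planted correlation strength", {
  dens <- vapply(c(0.2, 0.5, 0.8), function(r_target) {
    cfg <- synth_config(seed = 5, n_per_group = 30, groups = "A",
                        n_regions = 12, n_behaviors = 4, latent_strength = 0,
                        cluster_spec = list(list(regions = 1:8, r = r_target)))
    dat <- gen_brain_behavior(cfg)
    gc <- region_correlations(dat$activity, "A")
    mean(significance_mask(gc, 0.005)[upper.tri(gc$r)])
  }, numeric(1))
  expect_true(all(diff(dens) > 0))
})

test_that("joined networks share nodes and hit the requested edge count", {
  tb1 <- make_activity(n = 10, p = 10, seed = 6, group = "Ctrl")
  tb2 <- make_activity(n = 10, p = 10, seed = 7, group = "AD")
  tb <- rbind(tb1, tb2)
  corrs <- list(Ctrl = region_correlations(tb, "Ctrl"),
                AD = region_correlations(tb, "AD"))
  nets <- joined_network(corrs, edge_density = 1)
  expect_equal(nrow(nets$Ctrl$edges), 45)     # complete graph on 10 nodes
  nets <- joined_network(corrs, edge_density = 0.2)
  expect_equal(nrow(nets$AD$edges), round(0.2 * 45))
  expect_identical(nets$Ctrl$nodes, nets$AD$nodes)
  # edges are the smallest p-values of that group
  kept_p <- nets$AD$edges$p
  all_p <- corrs$AD$p[upper.tri(corrs$AD$p)]
  expect_lte(max(kept_p), sort(all_p)[nrow(nets$AD$edges)])
  expect_error(joined_network(corrs["AD"]), "2 groups")
  expect_error(joined_network(corrs, edge_density = 1e-6), "zero edges")
})

test_that("a cluster planted in one group dominates that group's network", {
  cfg_ad <- synth_config(seed = 8, n_per_group = 12, groups = "AD",
                         n_regions = 20, n_behaviors = 4, latent_strength = 0,
                         cluster_spec = list(list(regions = 1:6, r = 0.85)))
  cfg_ct <- synth_config(seed = 9, n_per_group = 12, groups = "Ctrl",
                         n_regions = 20, n_behaviors = 4, latent_strength = 0)
  ad <- gen_brain_behavior(cfg_ad)$activity
  ct <- gen_brain_behavior(cfg_ct)$activity
  ct$group <- "Ctrl"
  corrs <- list(AD = region_correlations(ad, "AD"),
                Ctrl = region_correlations(ct, "Ctrl"))
  nets <- joined_network(corrs, edge_density = 0.08)
  in_block <- function(net) {
    blk <- sprintf("region_%03d", 1:6)
    sum(net$edges$region_a %in% blk & net$edges$region_b %in% blk)
  }
  expect_gt(in_block(nets$AD), in_block(nets$Ctrl))
  expect_gte(in_block(nets$AD), 10)   # near-clique among the 6 planted regions
})

test_that("topology metrics reproduce closed-form values", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  m <- topology_metrics(adj_to_net(k4))
  expect_equal(unname(m), c(3, 1, 1, 0))
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  m <- topology_metrics(adj_to_net(p3))
  expect_equal(unname(m["mean_efficiency"]), 5 / 6)
  expect_equal(unname(m["mean_betweenness"]), 1 / 3)
  empty <- adj_to_net(matrix(0, 4, 4))
  expect_equal(unname(topology_metrics(empty)), c(0, 0, 0, 0))
  expect_error(topology_metrics(list(nodes = character(0),
                                     edges = data.frame())), "empty")
})

test_that("sweep curves are monotone where edge nesting implies it", {
  tb <- make_activity(n = 12, p = 15, seed = 10)
  gc <- region_correlations(tb, "A")
  sw <- threshold_sweep(gc, alpha_grid(15))
  expect_true(all(diff(sw$mean_degree) >= 0))
  expect_true(all(diff(sw$mean_efficiency) >= -1e-12))
  expect_true(all(is.finite(as.matrix(sw))))
  # the alpha = 1 endpoint equals the complete graph over all regions
  expect_equal(sw$mean_degree[15], 14)
  expect_equal(sw$mean_efficiency[15], 1)
  expect_error(threshold_sweep(gc, c(0.5, 0.1)), "sorted")
})

test_that("sweep results are bit-reproducible", {
  tb <- make_activity(n = 10, p = 10, seed = 11)
  gc <- region_correlations(tb, "A")
  expect_identical(threshold_sweep(gc), threshold_sweep(gc))
})

test_that("absolute-r distributions respect subset structure", {
  cfg <- synth_config(seed = 12, n_per_group = 25, groups = "A",
                      n_regions = 15, n_behaviors = 4, latent_strength = 0,
                      cluster_spec = list(list(regions = 1:5, r = 0.8)))
  dat <- gen_brain_behavior(cfg)
  gc <- region_correlations(dat$activity, "A")
  all_r <- abs_r_distribution(gc)
  expect_length(all_r, 15 * 14 / 2)
  blk <- sprintf("region_%03d", 1:5)
  sub_r <- abs_r_distribution(gc, blk)
  expect_length(sub_r, 10)
  expect_gt(mean(sub_r), mean(all_r))
  expect_error(abs_r_distribution(gc, "nope"), "unknown")
})
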