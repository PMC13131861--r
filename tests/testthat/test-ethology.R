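make_traj <- function(x, y, fps = 30, nose_x = NULL, nose_y = NULL) {
  n <- length(x)
  out <- data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) / fps,
                    x_cm = x, y_cm = y,
                    nose_x_cm = nose_x %||% x, nose_y_cm = nose_y %||% y)
  attr(out, "fps") <- fps
  out
}

test_that("zone occupancy counts time and entries per zone", {
  of <- of_geometry()
  still <- make_traj(rep(25, 300), rep(25, 300))
  occ <- zone_occupancy(still, of)
  expect_equal(occ$time_s[occ$zone == "center"], 10)
  expect_equal(occ$entries[occ$zone == "center"], 1)
  expect_equal(occ$time_s[occ$zone == "periphery"], 0)
  expect_equal(sum(occ$time_s), nrow(still) / 30)

  # center -> open arm -> center on the EPM: one open entry
  epm <- epm_geometry()
  path <- make_traj(c(0, 0, 10, 20, 10, 0, 0), rep(0, 7), fps = 1)
  occ <- zone_occupancy(path, epm)
  expect_equal(occ$entries[occ$zone == "open_right"], 1)
  expect_equal(occ$entries[occ$zone == "center"], 2)
  expect_equal(sum(occ$time_s), 7)
})

test_that("frame assignment matches a per-frame oracle and conserves time", {
  of <- of_geometry()
  set.seed(70)
  x <- runif(500, 0, 50); y <- runif(500, 0, 50)
  traj <- make_traj(x, y)
  occ <- zone_occupancy(traj, of)
  in_center <- x >= 10 & x <= 40 & y >= 10 & y <= 40
  expect_equal(occ$time_s[occ$zone == "center"], sum(in_center) / 30)
  expect_equal(occ$time_s[occ$zone == "periphery"], sum(!in_center) / 30)
  expect_equal(sum(occ$time_s), 500 / 30)
  # points outside every zone are flagged and attributed to the nearest zone
  out_traj <- make_traj(c(25, -5), c(25, 25))
  occ2 <- zone_occupancy(out_traj, of)
  expect_equal(attr(occ2, "n_outside_flagged"), 1)
  expect_equal(sum(occ2$time_s), 2 / 30)
  expect_equal(occ2$time_s[occ2$zone == "periphery"], 1 / 30)
})

test_that("distance traveled sums Euclidean steps", {
  still <- make_traj(rep(3, 50), rep(4, 50))
  expect_equal(distance_traveled(still)$total_cm, 0)
  # a straight 10 cm line, regardless of frame rate
  for (fps in c(15, 30, 60)) {
    n <- 10 * fps
    line <- make_traj(seq(0, 10, length.out = n), rep(25, n), fps = fps)
    expect_equal(distance_traveled(line)$total_cm, 10, tolerance = 1e-12)
  }
  set.seed(71)
  x <- cumsum(rnorm(600)); y <- cumsum(rnorm(600))
  traj <- make_traj(x, y, fps = 1)
  expect_equal(distance_traveled(traj)$total_cm,
               sum(sqrt(diff(x)^2 + diff(y)^2)), tolerance = 1e-12)
  dt <- distance_traveled(traj, bin_min = 5)
  expect_equal(sum(dt$bins$distance_cm), dt$total_cm, tolerance = 1e-12)
  expect_error(distance_traveled(make_traj(1, 1)), "2 frames")
})

test_that("absent-explorer screen requires both criteria", {
  epm <- epm_geometry()
  fps <- 30
  # fully immobile 300 s in a closed arm: excluded
  immobile <- make_traj(rep(0, 300 * fps), rep(15, 300 * fps))
  scr <- absent_explorer_screen(immobile, epm)
  expect_false(scr$keep)
  expect_true(scr$still$hit && scr$same_zone$hit)
  expect_length(scr$reasons, 2)

  # immobile 200 s, then active exploration across zones: criterion 2 fails
  n1 <- 200 * fps
  n2 <- 100 * fps
  tour_x <- c(rep(0, n1), seq(0, 20, length.out = n2 / 4),
              seq(20, -20, length.out = n2 / 4),
              seq(-20, 0, length.out = n2 / 4), rep(0, n2 / 4))
  tour_y <- c(rep(15, n1), rep(0, n2 / 2), rep(0, n2 / 4),
              seq(0, -15, length.out = n2 / 4))
  active <- make_traj(tour_x, tour_y)
  scr2 <- absent_explorer_screen(active, epm)
  expect_true(scr2$still$hit)
  expect_false(scr2$same_zone$hit)
  expect_true(scr2$keep)

  # never stationary 180 s: kept even when zone-bound
  set.seed(72)
  wander <- make_traj(pmin(pmax(cumsum(rnorm(300 * fps, sd = 0.2)), -3), 3),
                      rep(15, 300 * fps))
  scr3 <- absent_explorer_screen(wander, epm)
  expect_false(scr3$still$hit)
  expect_true(scr3$keep)
})

test_that("screen decision is frame-rate invariant for a fixed path", {
  epm <- epm_geometry()
  path_fun <- function(t) {     # immobile for 300 s in the closed arm
    cbind(rep(0, length(t)), rep(-15, length(t)))
  }
  decisions <- vapply(c(15, 30, 60), function(fps) {
    t <- seq(0, 300 - 1 / fps, by = 1 / fps)
    xy <- path_fun(t)
    absent_explorer_screen(make_traj(xy[, 1], xy[, 2], fps = fps), epm)$keep
  }, logical(1))
  expect_true(all(decisions == decisions[1]))
})

test_that("head dips count nose excursions into edge zones", {
  epm <- epm_geometry()
  fps <- 30
  n <- 10 * fps
  # nose stays on the arm midline: no dips
  mid <- make_traj(seq(5, 25, length.out = n), rep(0, n),
                   nose_x = seq(7, 27, length.out = n), nose_y = rep(0, n))
  hd <- head_dips(mid, epm)
  expect_equal(hd$count, 0)
  expect_equal(hd$total_duration_s, 0)

  # three scripted excursions over the north edge of the right open arm
  nose_y <- rep(0, n)
  for (k in 0:2) nose_y[(30 + k * 60):(45 + k * 60)] <- 5
  dips <- make_traj(rep(15, n), rep(0, n),
                    nose_x = rep(15, n), nose_y = nose_y)
  hd2 <- head_dips(dips, epm)
  expect_equal(hd2$count, 3)
  expect_equal(hd2$total_duration_s, 3 * 16 / fps)
  expect_error(head_dips(mid[, 1:4], epm), "nose")
})

test_that("syllable frequencies count onsets and normalize against references", {
  fps <- 30
  seq_ids <- c(1, 1, 2, 2, 2, 1, 3, 3, 1, 1)
  sf <- syllable_frequencies(seq_ids, fps = fps)
  expect_equal(sf$onsets[sf$syllable == 1], 3)
  expect_equal(sf$onsets[sf$syllable == 2], 1)
  expect_equal(sf$frequency_hz, sf$onsets / (length(seq_ids) / fps))
  expect_equal(sum(sf$occupancy), 1)

  ref <- c(`1` = sf$frequency_hz[1], `2` = 2 * sf$frequency_hz[2], `3` = 0)
  sf2 <- syllable_frequencies(seq_ids, fps = fps, reference_means = ref)
  expect_equal(sf2$log2_norm[sf2$syllable == 1], 0)    # equal to reference
  expect_equal(sf2$log2_norm[sf2$syllable == 2], -1)   # half the reference
  expect_true(is.na(sf2$log2_norm[sf2$syllable == 3])) # zero reference
  expect_true(sf2$undefined[sf2$syllable == 3])
})

test_that("syllable transition matrices are row-stochastic and oracle-exact", {
  m <- syllable_transition_matrix(c(1, 1, 2, 2, 1))
  expect_equal(m["1", "2"], 1)
  expect_equal(m["2", "1"], 1)
  cyc <- syllable_transition_matrix(rep(c(1, 2, 3), 10))
  expect_equal(unname(cyc["1", "2"]), 1)
  expect_equal(unname(cyc["2", "3"]), 1)
  expect_equal(unname(cyc["3", "1"]), 1)
  expect_equal(sum(cyc), 3)

  set.seed(73)
  s <- sample(1:5, 400, replace = TRUE)
  m2 <- syllable_transition_matrix(s)
  runs <- rle(s)$values
  for (a in 1:5) {
    out_a <- runs[-length(runs)] == a
    if (!any(out_a)) next
    for (b in setdiff(1:5, a)) {
      expect_equal(unname(m2[as.character(a), as.character(b)]),
                   sum(out_a & runs[-1] == b) / sum(out_a))
    }
  }
  rs <- rowSums(m2)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  expect_error(syllable_transition_matrix(rep(1, 10)), "distinct")
})
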