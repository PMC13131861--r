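# rectangles are c(xmin, xmax, ymin, ymax)
rect_contains <- function(rect, x, y) {
  x >= rect[1] & x <= rect[2] & y >= rect[3] & y <= rect[4]
}

rect_dist <- function(rect, x, y) {
  dx <- pmax(rect[1] - x, 0, x - rect[2])
  dy <- pmax(rect[3] - y, 0, y - rect[4])
  sqrt(dx^2 + dy^2)
}

zone_area <- function(zone) {
  sum(vapply(zone, function(r) (r[2] - r[1]) * (r[4] - r[3]), numeric(1)))
}

# zone name containing the point, or NA; zones are checked in list order
point_zone <- function(x, y, zones) {
  for (zn in names(zones)) {
    for (r in zones[[zn]]) if (rect_contains(r, x, y)) return(zn)
  }
  NA_character_
}

#' Open-field arena geometry
#'
#' A square open field divided by an evenly spaced 5 x 5 grid of 10 x 10 cm
#' cells; the centermost 3 x 3 block is the center zone and the outermost ring
#' of cells is the periphery. Coordinates are arena-frame cm with the origin
#' at a corner.
#'
#' @param size_cm side length of the arena (default 50).
#' @return object of class `zone_geometry` with zones `center` and
#'   `periphery`.
#' @export
of_geometry <- function(size_cm = 50) {
  cell <- size_cm / 5
  structure(list(
    type = "OF",
    zones = list(
      center = list(c(cell, size_cm - cell, cell, size_cm - cell)),
      periphery = list(
        c(0, size_cm, 0, cell),
        c(0, size_cm, size_cm - cell, size_cm),
        c(0, cell, cell, size_cm - cell),
        c(size_cm - cell, size_cm, cell, size_cm - cell)
      )
    ),
    dip_zones = NULL,
    start = c(size_cm / 2, size_cm / 2)
  ), class = "zone_geometry")
}

#' Elevated plus maze geometry
#'
#' Four arms around a square center platform: two open arms along the x axis
#' and two walled (closed) arms along the y axis. Head-dip zones of interest
#' are rectangular strips of width `dip_w` bordering each long edge and the
#' distal end of the open arms (just outside the arm footprint, where the
#' nose crosses during a head dip). Coordinates are arena-frame cm with the
#' origin at the maze center.
#'
#' @param arm_len arm length, cm (default 26.5).
#' @param arm_w arm width, cm (default 8).
#' @param center_w center platform side, cm (default 8).
#' @param dip_w head-dip strip width, cm (default 2).
#' @return object of class `zone_geometry` with zones `center`, `open_left`,
#'   `open_right`, `closed_top`, `closed_bottom`, plus `dip_zones`.
#' @export
epm_geometry <- function(arm_len = 26.5, arm_w = 8, center_w = 8, dip_w = 2) {
  h <- center_w / 2
  aw <- arm_w / 2
  ext <- h + arm_len
  dip_right <- list(
    c(h, ext, aw, aw + dip_w),
    c(h, ext, -aw - dip_w, -aw),
    c(ext, ext + dip_w, -aw, aw)
  )
  dip_left <- lapply(dip_right, function(r) c(-r[2], -r[1], r[3], r[4]))
  structure(list(
    type = "EPM",
    zones = list(
      center = list(c(-h, h, -h, h)),
      open_right = list(c(h, ext, -aw, aw)),
      open_left = list(c(-ext, -h, -aw, aw)),
      closed_top = list(c(-aw, aw, h, ext)),
      closed_bottom = list(c(-aw, aw, -ext, -h))
    ),
    dip_zones = list(dip_right = dip_right, dip_left = dip_left),
    start = c(0, 0)
  ), class = "zone_geometry")
}

# vectorized per-frame zone assignment; points outside every zone go to the
# nearest zone and are counted
assign_zones <- function(x, y, zones) {
  n <- length(x)
  zn <- names(zones)
  assigned <- rep(NA_character_, n)
  for (nm in zn) {
    inside <- rep(FALSE, n)
    for (r in zones[[nm]]) inside <- inside | rect_contains(r, x, y)
    assigned[is.na(assigned) & inside] <- nm
  }
  outside <- which(is.na(assigned))
  if (length(outside)) {
    dmat <- vapply(zn, function(nm) {
      do.call(pmin, lapply(zones[[nm]], rect_dist, x = x[outside], y = y[outside]))
    }, numeric(length(outside)))
    dmat <- matrix(dmat, nrow = length(outside))
    assigned[outside] <- zn[max.col(-dmat, ties.method = "first")]
  }
  list(zone = assigned, n_outside = length(outside))
}

#' Zone occupancy times and entries
#'
#' Assigns every frame to a zone (point-in-rectangle; frames outside every
#' zone are attributed to the nearest zone and counted in the
#' `n_outside_flagged` attribute), then reports per-zone time and entry
#' counts. An entry is counted at each change of zone into the zone; the
#' initial placement counts as the first entry.
#'
#' @param traj a trajectory data.frame (see [gen_trajectory()]) with
#'   attribute `fps`.
#' @param zones a [zone_geometry()].
#' @param keypoint `"centroid"` or `"nose"`.
#' @return data.frame (`zone`, `time_s`, `entries`) with attribute
#'   `n_outside_flagged`.
#' @export
zone_occupancy <- function(traj, zones, keypoint = c("centroid", "nose")) {
  keypoint <- match.arg(keypoint)
  fps <- attr(traj, "fps")
  if (is.null(fps)) stop("trajectory lacks an fps attribute")
  x <- if (keypoint == "nose") traj$nose_x_cm else traj$x_cm
  y <- if (keypoint == "nose") traj$nose_y_cm else traj$y_cm
  az <- assign_zones(x, y, zones$zones)
  runs <- rle(az$zone)
  zn <- names(zones$zones)
  out <- data.frame(
    zone = zn,
    time_s = vapply(zn, function(nm) sum(az$zone == nm) / fps, numeric(1)),
    entries = vapply(zn, function(nm) sum(runs$values == nm), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_outside_flagged") <- az$n_outside
  out
}

#' Distance traveled
#'
#' Total Euclidean path length of the centroid, optionally binned in time.
#'
#' @param traj a trajectory data.frame with attribute `fps`.
#' @param bin_min optional bin width in minutes for a per-bin breakdown.
#' @return list: `total_cm` and (when `bin_min` is given) `bins`, a
#'   data.frame (`bin`, `t_start_min`, `distance_cm`).
#' @export
distance_traveled <- function(traj, bin_min = NULL) {
  if (nrow(traj) < 2) stop("need at least 2 frames")
  steps <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)
  out <- list(total_cm = sum(steps))
  if (!is.null(bin_min)) {
    bin_idx <- floor(traj$t_s[-1] / (bin_min * 60))
    agg <- tapply(steps, bin_idx, sum)
    out$bins <- data.frame(
      bin = as.integer(names(agg)) + 1L,
      t_start_min = as.integer(names(agg)) * bin_min,
      distance_cm = as.numeric(agg)
    )
  }
  out
}

#' Absent-explorer exclusion screen
#'
#' Flags elevated-plus-maze trials in which the animal showed no investigative
#' behavior. A trial is excluded only when BOTH criteria hold:
#' (1) a maximal run of at least `still_s` seconds during which the centroid
#' stays within `pos_eps_cm` of the run-start position, and (2) a single zone
#' holding strictly more than `zone_frac` of the total test time and more
#' than `zone_s` seconds.
#'
#' @param traj a trajectory data.frame with attribute `fps`.
#' @param zones a [zone_geometry()].
#' @param still_s same-position criterion, seconds (default 180).
#' @param zone_frac same-zone fraction criterion (default 0.95).
#' @param zone_s same-zone absolute-time criterion, seconds (default 285).
#' @param pos_eps_cm displacement tolerance defining "same position", cm
#'   (default 1).
#' @return list: `keep` (logical), `still` and `same_zone` (per-criterion
#'   details), `reasons` (character, empty when kept).
#' @export
absent_explorer_screen <- function(traj, zones, still_s = 180,
                                   zone_frac = 0.95, zone_s = 285,
                                   pos_eps_cm = 1.0) {
  fps <- attr(traj, "fps")
  x <- traj$x_cm; y <- traj$y_cm
  n <- length(x)
  # anchored maximal still runs: a run starts at its anchor frame and extends
  # while the centroid stays within pos_eps_cm of the anchor position
  best_run <- 0
  i <- 1L
  while (i <= n) {
    j <- i + 1L
    while (j <= n && (x[j] - x[i])^2 + (y[j] - y[i])^2 <= pos_eps_cm^2) {
      j <- j + 1L
    }
    best_run <- max(best_run, (j - i) / fps)
    i <- j
  }
  occ <- zone_occupancy(traj, zones)
  total_s <- n / fps
  top <- which.max(occ$time_s)
  still_hit <- best_run >= still_s
  zone_hit <- occ$time_s[top] > zone_frac * total_s && occ$time_s[top] > zone_s
  exclude <- still_hit && zone_hit
  list(
    keep = !exclude,
    still = list(hit = still_hit, max_run_s = best_run),
    same_zone = list(hit = zone_hit, zone = occ$zone[top],
                     time_s = occ$time_s[top], total_s = total_s),
    reasons = if (exclude) {
      c(sprintf("still for %.1f s (>= %g s) in the same position", best_run, still_s),
        sprintf("%.1f s (%.1f%%) in zone '%s'", occ$time_s[top],
                100 * occ$time_s[top] / total_s, occ$zone[top]))
    } else character(0)
  )
}

#' Head-dip events over open-arm edges
#'
#' Counts nose entries into the edge-bordering head-dip rectangles of an
#' elevated plus maze and sums the time the nose spends there.
#'
#' @param traj a trajectory data.frame with nose keypoints and attribute
#'   `fps`.
#' @param zones an [epm_geometry()] (must carry `dip_zones`).
#' @return list: `count`, `total_duration_s`.
#' @export
head_dips <- function(traj, zones) {
  if (is.null(traj$nose_x_cm)) stop("trajectory lacks a nose keypoint")
  if (is.null(zones$dip_zones)) stop("geometry has no head-dip zones")
  fps <- attr(traj, "fps")
  rects <- unlist(zones$dip_zones, recursive = FALSE)
  inside <- rep(FALSE, nrow(traj))
  for (r in rects) {
    inside <- inside | rect_contains(r, traj$nose_x_cm, traj$nose_y_cm)
  }
  runs <- rle(inside)
  list(count = sum(runs$values),
       total_duration_s = sum(inside) / fps)
}

#' Syllable expression frequencies
#'
#' Frequency of each behavioral syllable as onset events per second (an onset
#' is a frame where the syllable id differs from the previous frame, plus the
#' first frame), with the occupancy fraction as a companion measure. When
#' reference means are supplied (e.g. the control-group mean frequency per
#' syllable), a normalized value `log2(frequency / reference)` is added;
#' syllables with a zero reference (or zero observed frequency) get NA and
#' are flagged.
#'
#' @param seq integer vector of per-frame syllable ids.
#' @param fps frame rate, Hz.
#' @param reference_means optional named numeric vector of reference
#'   frequencies, names = syllable ids.
#' @return data.frame: `syllable`, `onsets`, `frequency_hz`, `occupancy`,
#'   and with references `log2_norm` + `undefined` flag.
#' @export
syllable_frequencies <- function(seq, fps = 30, reference_means = NULL) {
  if (length(seq) == 0) stop("empty sequence")
  duration_s <- length(seq) / fps
  onset <- c(TRUE, diff(seq) != 0)
  ids <- sort(unique(seq))
  onsets <- vapply(ids, function(s) sum(onset & seq == s), numeric(1))
  out <- data.frame(
    syllable = ids,
    onsets = as.integer(onsets),
    frequency_hz = onsets / duration_s,
    occupancy = vapply(ids, function(s) mean(seq == s), numeric(1))
  )
  if (!is.null(reference_means)) {
    ref <- reference_means[as.character(ids)]
    ratio <- out$frequency_hz / as.numeric(ref)
    ok <- !is.na(ratio) & ratio > 0 & is.finite(ratio)
    out$log2_norm <- ifelse(ok, log2(ratio), NA_real_)
    out$undefined <- !ok
  }
  out
}

#' Syllable transition probability matrix
#'
#' Probabilities of each incoming syllable given the current (outgoing)
#' syllable. Frame-to-frame persistence is excluded: the sequence is collapsed
#' to its run values and transitions counted at syllable changes, then rows
#' are normalized to sum to 1. Rows with no outgoing transitions are left as
#' zeros and flagged.
#'
#' @param seq integer vector of per-frame syllable ids (>= 2 distinct).
#' @return row-stochastic matrix (outgoing x incoming) with attribute
#'   `zero_rows` naming flagged rows.
#' @export
syllable_transition_matrix <- function(seq) {
  ids <- sort(unique(seq))
  if (length(ids) < 2) stop("need at least 2 distinct syllables")
  runs <- rle(seq)$values
  k <- length(ids)
  m <- matrix(0, k, k, dimnames = list(outgoing = ids, incoming = ids))
  if (length(runs) >= 2) {
    from <- match(runs[-length(runs)], ids)
    to <- match(runs[-1], ids)
    for (i in seq_along(from)) m[from[i], to[i]] <- m[from[i], to[i]] + 1
  }
  rs <- rowSums(m)
  zero_rows <- ids[rs == 0]
  rs[rs == 0] <- 1
  m <- m / rs
  attr(m, "zero_rows") <- zero_rows
  m
}
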