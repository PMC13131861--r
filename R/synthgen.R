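#' Configuration for the synthetic brain-behavior generator
#'
#' Bundles the design of a simulated activity-mapping cohort: group labels and
#' sizes, the dimensionality of the behavior and brain-region blocks, a planted
#' low-rank cross-block covariance, optional region clusters with a target
#' within-cluster correlation, and a missing-completely-at-random rate for the
#' region block.
#'
#' The generator is a Gaussian factor model: per subject, `latent_rank` shared
#' standard-normal factors load (scaled by `latent_strength`) on designated
#' behavior and region subsets, plus independent Gaussian noise with standard
#' deviation `noise_sd`. Cluster factors are added on top for each
#' `cluster_spec` entry, with the factor scale chosen in closed form so that
#' the within-cluster correlation equals the requested target:
#' `|r| = s^2 / (s^2 + noise_sd^2)` gives `s = noise_sd * sqrt(t / (1 - t))`.
#'
#' @param seed integer seed; fans out to independent per-generator streams.
#' @param n_per_group subjects per group (>= 3).
#' @param groups character vector of group labels.
#' @param n_regions number of brain regions (activity density columns).
#' @param n_behaviors number of behavioral features.
#' @param latent_rank rank of the planted cross-block covariance
#'   (< min(n_regions, n_behaviors)).
#' @param latent_strength scale of the shared factors; 0 plants no
#'   brain-behavior covariance (a global null).
#' @param behavior_idx,region_idx integer vectors (or lists of vectors, one
#'   per latent component) naming which columns carry the planted loading.
#'   Defaults: the first `ceiling(n/3)` columns of each block.
#' @param cluster_spec list of `list(regions = <idx>, r = <target |r|>)`
#'   entries planting correlated region clusters. Targets must be in [0, 1).
#' @param missing_rate MCAR missingness fraction for the region block, in
#'   [0, 1).
#' @param noise_sd independent noise standard deviation (arbitrary units).
#' @return an object of class `synth_config`.
#' @seealso [gen_brain_behavior()]
#' @export
synth_config <- function(seed,
                         n_per_group = 8,
                         groups = c("Ctrl Sunrise", "Ctrl Sundown",
                                    "AD Sunrise", "AD Sundown"),
                         n_regions = 137,
                         n_behaviors = 12,
                         latent_rank = 1,
                         latent_strength = 1,
                         behavior_idx = NULL,
                         region_idx = NULL,
                         cluster_spec = NULL,
                         missing_rate = 0,
                         noise_sd = 1) {
  if (n_per_group < 3) stop("n_per_group must be >= 3")
  if (latent_rank >= min(n_regions, n_behaviors)) {
    stop("latent_rank must be < min(n_regions, n_behaviors)")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!is.null(cluster_spec)) {
    for (cl in cluster_spec) {
      if (is.null(cl$regions) || is.null(cl$r)) {
        stop("each cluster_spec entry needs $regions and $r")
      }
      if (cl$r < 0 || cl$r >= 1) stop("cluster |r| target must be in [0, 1)")
      if (any(cl$regions < 1 | cl$regions > n_regions)) {
        stop("cluster_spec region index out of range")
      }
    }
  }
  as_idx_list <- function(idx, p, rank) {
    if (is.null(idx)) idx <- seq_len(ceiling(p / 3))
    if (!is.list(idx)) idx <- rep(list(idx), rank)
    if (length(idx) != rank) stop("need one loading index set per latent component")
    idx
  }
  structure(list(
    seed = as.integer(seed), n_per_group = n_per_group, groups = groups,
    n_regions = n_regions, n_behaviors = n_behaviors,
    latent_rank = latent_rank, latent_strength = latent_strength,
    behavior_idx = as_idx_list(behavior_idx, n_behaviors, latent_rank),
    region_idx = as_idx_list(region_idx, n_regions, latent_rank),
    cluster_spec = cluster_spec, missing_rate = missing_rate,
    noise_sd = noise_sd
  ), class = "synth_config")
}

#' Generate a synthetic activity-mapping cohort
#'
#' Draws a behavior table and a region activity-density table with the
#' factor-model structure described in [synth_config()], plus a ground-truth
#' record of what was planted. Activity densities are expressed around an
#' arbitrary baseline of 100 cells/mm^3 (clipped at zero) so the tables
#' satisfy the non-negativity expected of volume-normalized counts; adding a
#' constant leaves every correlation-based downstream stage unchanged.
#'
#' @param config a [synth_config()] object.
#' @return list with elements `behavior` (data.frame: subject_id, group,
#'   feature columns), `activity` (data.frame: subject_id, group, region
#'   columns, possibly NA), and `truth` (planted loadings, cluster members,
#'   null feature names).
#' @examples
#' cfg <- synth_config(seed = 1, n_per_group = 6, n_regions = 20,
#'                     n_behaviors = 8)
#' dat <- gen_brain_behavior(cfg)
#' dim(dat$activity)
#' @export
gen_brain_behavior <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$seed, "brain_behavior"))
  n <- config$n_per_group * length(config$groups)
  p_b <- config$n_behaviors
  p_r <- config$n_regions
  rank <- config$latent_rank

  # unit-norm loading vectors supported on the designated subsets
  load_vec <- function(p, idx) {
    v <- numeric(p)
    v[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) / sqrt(length(idx))
    v
  }
  U0 <- vapply(config$behavior_idx, function(i) load_vec(p_b, i), numeric(p_b))
  V0 <- vapply(config$region_idx, function(i) load_vec(p_r, i), numeric(p_r))
  U0 <- matrix(U0, nrow = p_b)
  V0 <- matrix(V0, nrow = p_r)

  Z <- matrix(stats::rnorm(n * rank), n, rank)
  X <- config$latent_strength * (Z %*% t(U0)) +
    config$noise_sd * matrix(stats::rnorm(n * p_b), n, p_b)
  Y <- config$latent_strength * (Z %*% t(V0)) +
    config$noise_sd * matrix(stats::rnorm(n * p_r), n, p_r)

  cluster_members <- list()
  if (!is.null(config$cluster_spec)) {
    for (ci in seq_along(config$cluster_spec)) {
      cl <- config$cluster_spec[[ci]]
      s <- config$noise_sd * sqrt(cl$r / (1 - cl$r))
      g <- stats::rnorm(n)
      Y[, cl$regions] <- Y[, cl$regions] + s * g
      cluster_members[[ci]] <- cl$regions
    }
  }

  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n * p_r) < config$missing_rate, n, p_r)
    Y[drop] <- NA_real_
  }

  baseline <- 100
  X <- pmax(X + baseline, 0)
  Y <- pmax(Y + baseline, 0)

  behaviors <- sprintf("beh_%02d", seq_len(p_b))
  regions <- sprintf("region_%03d", seq_len(p_r))
  subjects <- sprintf("m%03d", seq_len(n))
  group <- rep(config$groups, each = config$n_per_group)
  colnames(X) <- behaviors
  colnames(Y) <- regions

  loaded_b <- sort(unique(unlist(config$behavior_idx)))
  loaded_r <- sort(unique(unlist(config$region_idx)))
  null_b <- if (config$latent_strength > 0) behaviors[-loaded_b] else behaviors
  null_r <- if (config$latent_strength > 0) regions[-loaded_r] else regions

  list(
    behavior = data.frame(subject_id = subjects, group = group, X,
                          stringsAsFactors = FALSE),
    activity = data.frame(subject_id = subjects, group = group, Y,
                          stringsAsFactors = FALSE),
    truth = list(behavior_loadings = U0, region_loadings = V0,
                 cluster_members = cluster_members,
                 null_behaviors = null_b, null_regions = null_r)
  )
}

#' Generate class-separable behavioral feature tables
#'
#' Draws a labeled feature table in which a designated subset of features
#' carries class-dependent mean shifts (Gaussian class means of scale
#' `effect_size`) while the remaining features are pure noise — the planted
#' analogue of a behavioral dataset where only a few movement-syllable
#' frequencies distinguish the groups.
#'
#' @param seed integer seed.
#' @param n_per_class subjects per class.
#' @param classes class labels.
#' @param n_features number of feature columns.
#' @param signal_idx indices of the features carrying class signal.
#' @param effect_size standard deviation of the class-mean shifts, in noise
#'   units.
#' @param noise_sd within-class feature standard deviation.
#' @return list with `data` (data.frame: subject_id, class, features) and
#'   `truth` (class means, signal feature names).
#' @export
gen_labeled_features <- function(seed, n_per_class = 10,
                                 classes = c("Ctrl Sunrise", "Ctrl Sundown",
                                             "AD Sunrise", "AD Sundown"),
                                 n_features = 12, signal_idx = 1:3,
                                 effect_size = 2, noise_sd = 1) {
  set.seed(child_seed(seed, "labeled_features"))
  k <- length(classes)
  n <- k * n_per_class
  M <- matrix(0, k, n_features)
  M[, signal_idx] <- effect_size * matrix(stats::rnorm(k * length(signal_idx)),
                                          k, length(signal_idx))
  cls <- rep(classes, each = n_per_class)
  Xm <- M[rep(seq_len(k), each = n_per_class), , drop = FALSE] +
    noise_sd * matrix(stats::rnorm(n * n_features), n, n_features)
  feats <- sprintf("feat_%02d", seq_len(n_features))
  colnames(Xm) <- feats
  list(
    data = data.frame(subject_id = sprintf("m%03d", seq_len(n)), class = cls,
                      Xm, stringsAsFactors = FALSE),
    truth = list(class_means = M, signal_features = feats[signal_idx])
  )
}

#' Generate a sinusoidal activity trace
#'
#' Emulates piezo-derived locomotor activity in fixed time bins:
#' `mesor + amplitude * cos(2 * pi * (t - acrophase) / period)` plus Gaussian
#' noise, clipped at zero. Times are zeitgeber hours (ZT0 = lights-on).
#'
#' @param period_h rhythm period in hours.
#' @param amplitude oscillation amplitude (activity units, >= 0).
#' @param mesor rhythm-adjusted mean (activity units).
#' @param acrophase_h peak time in ZT hours.
#' @param noise_sd Gaussian noise standard deviation (activity units).
#' @param n_days number of 24-h days to simulate.
#' @param bin_min bin width in minutes; must divide 1440.
#' @param seed integer seed.
#' @return data.frame (`zt_hours`, `activity`) with attribute `bin_min`.
#' @seealso [cosinor_fit()]
#' @export
gen_activity_trace <- function(period_h = 24, amplitude = 0.1, mesor = 0.15,
                               acrophase_h = 18, noise_sd = 0.02, n_days = 5,
                               bin_min = 10, seed = 1) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (1440 %% bin_min != 0) stop("bin_min must divide 24 * 60 minutes")
  set.seed(child_seed(seed, "activity"))
  t_h <- seq(0, n_days * 24 - bin_min / 60, by = bin_min / 60)
  y <- mesor + amplitude * cos(2 * pi * (t_h - acrophase_h) / period_h)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
  out <- data.frame(zt_hours = t_h, activity = pmax(y, 0))
  attr(out, "bin_min") <- bin_min
  out
}

#' Construct a hypnogram object
#'
#' @param states character vector of per-epoch vigilance states
#'   (`"Wake"`, `"NREM"`, `"REM"`).
#' @param epoch_s epoch duration in seconds.
#' @param start_zt zeitgeber time of the first epoch, hours.
#' @return data.frame (`epoch`, `zt_hours`, `state`) of class `hypnogram`
#'   with attributes `epoch_s` and `start_zt`.
#' @export
hypnogram <- function(states, epoch_s, start_zt = 0) {
  states <- as.character(states)
  bad <- setdiff(unique(states), c("Wake", "NREM", "REM"))
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "))
  out <- data.frame(
    epoch = seq_along(states),
    zt_hours = start_zt + (seq_along(states) - 1) * epoch_s / 3600,
    state = states, stringsAsFactors = FALSE
  )
  attr(out, "epoch_s") <- epoch_s
  attr(out, "start_zt") <- start_zt
  class(out) <- c("hypnogram", "data.frame")
  out
}

#' Generate a three-state hypnogram
#'
#' Semi-Markov simulation of Wake/NREM/REM vigilance states with geometric
#' dwell times (per-state mean bout lengths) and phase-dependent entry
#' probabilities. REM is entered only from NREM, so the only transitions that
#' can occur are W-N, N-R, N-W, R-N and R-W. Setting the REM dwell mean to a
#' non-finite value removes REM from the state space entirely.
#'
#' @param dwell_params named numeric vector of mean bout lengths in seconds
#'   for `Wake`, `NREM`, `REM`; each finite value must be >= `epoch_s`.
#' @param phase_bias list with `light` and `dark` named multipliers applied to
#'   state entry probabilities (light = ZT0-12, dark = ZT12-24).
#' @param epoch_s epoch length in seconds.
#' @param n_hours record length in hours.
#' @param start_zt zeitgeber time of the first epoch.
#' @param seed integer seed.
#' @return a [hypnogram()].
#' @export
gen_hypnogram <- function(dwell_params = c(Wake = 600, NREM = 360, REM = 90),
                          phase_bias = list(
                            light = c(Wake = 0.5, NREM = 1.5, REM = 1.5),
                            dark = c(Wake = 2.0, NREM = 0.7, REM = 0.7)
                          ),
                          epoch_s = 4, n_hours = 24, start_zt = 0, seed = 1) {
  if (epoch_s <= 0) stop("epoch_s must be positive")
  states <- c("Wake", "NREM", "REM")
  if (!all(states %in% names(dwell_params))) {
    stop("dwell_params must name Wake, NREM and REM")
  }
  rem_excluded <- !is.finite(dwell_params[["REM"]])
  finite_states <- if (rem_excluded) c("Wake", "NREM") else states
  if (any(dwell_params[finite_states] < epoch_s)) {
    stop("dwell means must be >= epoch_s")
  }
  set.seed(child_seed(seed, "hypnogram"))
  n_epochs <- floor(n_hours * 3600 / epoch_s)

  # admissible next states; REM reachable only from NREM
  entries <- list(
    Wake = c(NREM = 1),
    NREM = c(REM = 0.35, Wake = 0.65),
    REM  = c(NREM = 0.6, Wake = 0.4)
  )
  out <- character(n_epochs)
  i <- 1L
  state <- "Wake"
  while (i <= n_epochs) {
    p_leave <- min(1, epoch_s / dwell_params[[state]])
    len <- stats::rgeom(1L, p_leave) + 1L
    len <- min(len, n_epochs - i + 1L)
    out[i:(i + len - 1L)] <- state
    i <- i + len
    if (i > n_epochs) break
    zt <- (start_zt + (i - 1) * epoch_s / 3600) %% 24
    phase <- if (zt < 12) "light" else "dark"
    cand <- entries[[state]]
    if (rem_excluded) cand <- cand[names(cand) != "REM"]
    w <- cand * phase_bias[[phase]][names(cand)]
    w <- w / sum(w)
    state <- sample(names(w), 1L, prob = w)
  }
  hypnogram(out, epoch_s = epoch_s, start_zt = start_zt)
}

#' Default per-state EEG band-weight profiles
#'
#' Relative spectral weight of each classical EEG band per vigilance state:
#' NREM is delta-dominant (slow-wave activity), REM is theta-dominant, Wake is
#' broadband and desynchronized.
#'
#' @return named list of per-state band weight vectors.
#' @export
default_band_profiles <- function() {
  list(
    Wake = c(delta = 1.0, theta = 1.0, alpha = 1.0, beta = 1.0, gamma = 1.0),
    NREM = c(delta = 8.0, theta = 1.0, alpha = 0.5, beta = 0.3, gamma = 0.2),
    REM  = c(delta = 1.0, theta = 8.0, alpha = 0.5, beta = 0.3, gamma = 0.2)
  )
}

#' Generate an EEG/EMG recording from a hypnogram
#'
#' Per epoch, the EEG channel is spectrally shaped Gaussian noise whose band
#' power follows the state's band-weight profile (shaping is applied in the
#' frequency domain with a piecewise-constant weight over the classical
#' bands); each epoch is scaled to a common RMS amplitude so that states
#' differ in spectral content, not total power. The EMG channel is white
#' noise at the state's RMS level (high in Wake, low in sleep).
#'
#' @param hyp a [hypnogram()].
#' @param fs sampling rate, Hz (>= 100).
#' @param band_profiles per-state named band weights; see
#'   [default_band_profiles()].
#' @param emg_levels per-state EMG RMS (arbitrary microvolt units).
#' @param eeg_rms common EEG RMS per epoch.
#' @param seed integer seed.
#' @return object of class `eeg_recording`: list with `eeg`, `emg`, `fs`,
#'   `start_zt`.
#' @seealso [sliding_spectrogram()], [score_states()]
#' @export
gen_eeg <- function(hyp, fs = 200, band_profiles = default_band_profiles(),
                    emg_levels = c(Wake = 3, NREM = 0.5, REM = 0.3),
                    eeg_rms = 10, seed = 1) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (fs < 100) stop("fs must be >= 100 Hz")
  epoch_s <- attr(hyp, "epoch_s")
  n_ep <- nrow(hyp)
  n_samp <- round(epoch_s * fs)
  set.seed(child_seed(seed, "eeg"))

  bands <- eeg_bands()
  freq <- c(0:(n_samp %/% 2), -((n_samp - n_samp %/% 2 - 1):1)) * fs / n_samp
  af <- abs(freq)
  weight_for_state <- function(w) {
    out <- rep(0.05, n_samp)            # residual weight outside 0.1-50 Hz
    out[af < 0.1] <- 0
    for (b in seq_len(nrow(bands))) {
      out[af >= bands$lo[b] & af <= bands$hi[b]] <- w[[bands$band[b]]]
    }
    out[af > 30 & af < 30.1] <- w[["beta"]]   # printed band gap: bridge with beta
    out[af > 50] <- 0.05
    out
  }
  wts <- lapply(band_profiles, weight_for_state)

  eeg <- numeric(n_ep * n_samp)
  emg <- numeric(n_ep * n_samp)
  for (i in seq_len(n_ep)) {
    st <- hyp$state[i]
    x <- stats::rnorm(n_samp)
    xc <- Re(stats::fft(stats::fft(x) * sqrt(wts[[st]]), inverse = TRUE)) / n_samp
    xc <- xc * eeg_rms / sqrt(mean(xc^2))
    sl <- ((i - 1) * n_samp + 1):(i * n_samp)
    eeg[sl] <- xc
    emg[sl] <- stats::rnorm(n_samp, sd = emg_levels[[st]])
  }
  structure(list(eeg = eeg, emg = emg, fs = fs,
                 start_zt = attr(hyp, "start_zt")),
            class = "eeg_recording")
}

#' Generate an arena trajectory with zone preferences
#'
#' Bounded correlated random walk over a [zone_geometry()] arena whose
#' long-run zone occupancy approaches the requested per-zone fractions. The
#' walk is a Metropolis sampler targeting a density proportional to
#' `zone_pref / zone area` within each zone, so occupancy converges to
#' `zone_pref` (normalized) rather than to area-weighted preference. Emits a
#' centroid and a nose keypoint (nose leads the centroid by `nose_cm` along
#' the current heading and may cross arena edges, which is how head dips over
#' open-arm edges arise).
#'
#' @param arena a [zone_geometry()].
#' @param zone_pref named non-negative occupancy weights over the arena's
#'   zones.
#' @param step_sd per-axis proposal standard deviation, cm per frame.
#' @param duration_s recording length, seconds.
#' @param fps frame rate, Hz.
#' @param nose_cm centroid-to-nose distance, cm.
#' @param seed integer seed.
#' @return data.frame (`frame`, `t_s`, `x_cm`, `y_cm`, `nose_x_cm`,
#'   `nose_y_cm`) with attributes `fps` and `arena`.
#' @export
gen_trajectory <- function(arena, zone_pref, step_sd = 2, duration_s = 300,
                           fps = 30, nose_cm = 2, seed = 1) {
  stopifnot(inherits(arena, "zone_geometry"))
  if (fps <= 0) stop("fps must be positive")
  if (any(zone_pref < 0)) stop("zone_pref weights must be >= 0")
  zn <- names(arena$zones)
  if (!all(names(zone_pref) %in% zn)) {
    stop("unknown zone in zone_pref: ",
         paste(setdiff(names(zone_pref), zn), collapse = ", "))
  }
  pref <- stats::setNames(numeric(length(zn)), zn)
  pref[names(zone_pref)] <- zone_pref
  if (sum(pref) <= 0) stop("zone_pref must have positive total weight")
  pref <- pref / sum(pref)
  dens <- pref / vapply(arena$zones, zone_area, numeric(1))

  set.seed(child_seed(seed, "trajectory"))
  n <- round(duration_s * fps)
  x <- numeric(n); y <- numeric(n)
  cur <- arena$start
  cur_d <- dens[[point_zone(cur[1], cur[2], arena$zones)]]
  for (i in seq_len(n)) {
    prop <- cur + stats::rnorm(2, sd = step_sd)
    z <- point_zone(prop[1], prop[2], arena$zones)
    if (!is.na(z)) {
      d_new <- dens[[z]]
      accept <- if (cur_d <= 0) d_new > 0 else stats::runif(1) < d_new / cur_d
      if (isTRUE(accept)) {
        cur <- prop
        cur_d <- d_new
      }
    }
    x[i] <- cur[1]; y[i] <- cur[2]
  }
  heading <- hx_path(x, y)
  out <- data.frame(
    frame = seq_len(n), t_s = (seq_len(n) - 1) / fps,
    x_cm = x, y_cm = y,
    nose_x_cm = x + nose_cm * heading$ux,
    nose_y_cm = y + nose_cm * heading$uy
  )
  attr(out, "fps") <- fps
  attr(out, "arena") <- arena$type
  out
}

# unit heading along the path (last nonzero displacement, forward-filled)
hx_path <- function(x, y) {
  n <- length(x)
  ux <- c(0, diff(x)); uy <- c(0, diff(y))
  nrm <- sqrt(ux^2 + uy^2)
  ok <- nrm > 0
  ux[ok] <- ux[ok] / nrm[ok]; uy[ok] <- uy[ok] / nrm[ok]
  lastx <- 1; lasty <- 0
  for (i in seq_len(n)) {
    if (ok[i]) { lastx <- ux[i]; lasty <- uy[i] } else { ux[i] <- lastx; uy[i] <- lasty }
  }
  list(ux = ux, uy = uy)
}
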