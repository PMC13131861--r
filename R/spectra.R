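#' Classical EEG frequency bands
#'
#' Band limits as conventionally printed for rodent EEG: delta 0.1-4 Hz,
#' theta 4-10 Hz, alpha 10-13 Hz, beta 13.1-30 Hz, gamma 30.1-50 Hz. The
#' small gaps between beta/gamma and their neighbors are preserved as
#' printed; grid frequencies falling in a gap belong to neither band.
#'
#' @return data.frame: `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(0.1, 4, 10, 13.1, 30.1),
    hi = c(4, 10, 13, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' Sliding-window spectrogram
#'
#' Hann-tapered one-sided periodogram over a sliding window (default 5 s,
#' stepped by 2 s), giving a frequency resolution of `1 / window_s` (0.2 Hz at
#' the default). The number of bins is `floor((T - window) / step) + 1`.
#'
#' @param rec an `eeg_recording` (see [gen_eeg()]) or any list with `eeg`,
#'   `fs` and optionally `start_zt`.
#' @param window_s window length, seconds.
#' @param step_s step between window starts, seconds.
#' @return object of class `spectrogram`: `power` (frequency x bin, uV^2/Hz),
#'   `freq` (Hz), `t_start_s`, `t_center_s`, `window_s`, `step_s`, `fs`,
#'   `start_zt`.
#' @export
sliding_spectrogram <- function(rec, window_s = 5, step_s = 2) {
  x <- rec$eeg
  fs <- rec$fs
  wlen <- round(window_s * fs)
  step <- round(step_s * fs)
  n <- length(x)
  if (n < wlen) stop("record shorter than one window")
  nbins <- floor((n - wlen) / step) + 1
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))   # Hann taper
  starts <- (seq_len(nbins) - 1) * step
  seg <- matrix(x[outer(seq_len(wlen), starts, "+")], nrow = wlen)
  seg <- seg * w
  sp <- stats::mvfft(seg)
  nfreq <- wlen %/% 2 + 1
  pw <- (Mod(sp[seq_len(nfreq), , drop = FALSE])^2) / (fs * sum(w^2))
  if (nfreq > 2) pw[2:(nfreq - 1), ] <- 2 * pw[2:(nfreq - 1), ]
  if (wlen %% 2 == 1) pw[nfreq, ] <- 2 * pw[nfreq, ]
  structure(list(
    power = pw,
    freq = (seq_len(nfreq) - 1) * fs / wlen,
    t_start_s = starts / fs,
    t_center_s = starts / fs + window_s / 2,
    window_s = window_s, step_s = step_s, fs = fs,
    start_zt = if (is.null(rec$start_zt)) 0 else rec$start_zt
  ), class = "spectrogram")
}

#' Per-bin EMG root-mean-square
#'
#' RMS of the EMG channel over the same sliding windows as
#' [sliding_spectrogram()], for use as the muscle-tone feature in
#' [score_states()].
#'
#' @param rec an `eeg_recording` with an `emg` channel.
#' @inheritParams sliding_spectrogram
#' @return numeric vector, one RMS value per bin.
#' @export
emg_bin_rms <- function(rec, window_s = 5, step_s = 2) {
  x <- rec$emg
  fs <- rec$fs
  wlen <- round(window_s * fs)
  step <- round(step_s * fs)
  if (length(x) < wlen) stop("record shorter than one window")
  nbins <- floor((length(x) - wlen) / step) + 1
  starts <- (seq_len(nbins) - 1) * step
  vapply(starts, function(s) sqrt(mean(x[(s + 1):(s + wlen)]^2)), numeric(1))
}

# summed band power per bin over [lo, hi] (inclusive)
band_power_bins <- function(spec, lo, hi) {
  sel <- spec$freq >= lo & spec$freq <= hi
  colSums(spec$power[sel, , drop = FALSE])
}

#' Rule-based sleep staging
#'
#' Classifies each spectrogram bin into Wake, NREM or REM from three z-scored
#' features: EMG RMS, delta-band power (0.1-4 Hz) and the theta/delta power
#' ratio. The rule mirrors conventional scoring criteria — high muscle tone
#' means Wake; among low-EMG bins, a high theta/delta ratio means REM and the
#' remainder (synchronized, delta-dominated EEG) is NREM:
#' EMG z-score above `theta_emg` gives Wake; otherwise a theta/delta z-score
#' above `theta_ratio` gives REM; otherwise NREM. An optional 3-bin majority
#' smoothing removes single-bin flickers.
#'
#' @param spec a [sliding_spectrogram()].
#' @param emg_rms per-bin EMG RMS, from [emg_bin_rms()]; must align with the
#'   spectrogram bins.
#' @param theta_emg Wake threshold on the z-scored EMG (default +0.5 SD).
#' @param theta_ratio REM threshold on the z-scored theta/delta ratio
#'   (default +1.0 SD).
#' @param smooth apply 3-bin majority smoothing (default TRUE).
#' @return a [hypnogram()] with one epoch per bin (`epoch_s = step_s`).
#' @export
score_states <- function(spec, emg_rms, theta_emg = 0.5, theta_ratio = 1.0,
                         smooth = TRUE) {
  stopifnot(inherits(spec, "spectrogram"))
  nbins <- ncol(spec$power)
  if (length(emg_rms) != nbins) stop("EMG bins do not align with spectrogram bins")
  delta <- band_power_bins(spec, 0.1, 4)
  theta <- band_power_bins(spec, 4, 10)
  # staging features are relative (z-scored over the record), so scoring
  # needs a mixture of states; a feature with zero spread is uninformative
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  z_emg <- zs(emg_rms)
  z_ratio <- zs(theta / delta)
  states <- ifelse(z_emg > theta_emg, "Wake",
                   ifelse(z_ratio > theta_ratio, "REM", "NREM"))
  if (smooth && nbins >= 3) {
    sm <- states
    for (i in 2:(nbins - 1)) {
      win <- states[(i - 1):(i + 1)]
      tab <- table(win)
      if (max(tab) >= 2) sm[i] <- names(tab)[which.max(tab)]
    }
    states <- sm
  }
  hypnogram(states, epoch_s = spec$step_s,
            start_zt = spec$start_zt + spec$t_start_s[1] / 3600)
}

#' Normalized average power spectrum
#'
#' Averages spectrogram power over a chosen set of bins (e.g. all bins scored
#' NREM), normalizes each frequency by the mean power across 0.1-50 Hz (so the
#' pre-log normalized power averages to exactly 1 over that range, making the
#' spectrum scale-invariant) and applies a log2 transform.
#'
#' @param spec a [sliding_spectrogram()].
#' @param state_mask logical vector (or integer indices) selecting bins to
#'   average; must select at least one bin.
#' @return data.frame (`frequency`, `log2_power`) restricted to 0.1-50 Hz,
#'   with the pre-log normalized power in attribute `normalized_power`.
#' @export
normalize_spectrum <- function(spec, state_mask) {
  stopifnot(inherits(spec, "spectrogram"))
  sel_bins <- if (is.logical(state_mask)) which(state_mask) else state_mask
  if (length(sel_bins) == 0) stop("state_mask selects no bins")
  avg <- rowMeans(spec$power[, sel_bins, drop = FALSE])
  in_range <- spec$freq >= 0.1 & spec$freq <= 50
  f <- spec$freq[in_range]
  norm <- avg[in_range] / mean(avg[in_range])
  out <- data.frame(frequency = f, log2_power = log2(norm))
  attr(out, "normalized_power") <- norm
  out
}

#' Band area under the normalized spectrum
#'
#' Trapezoidal integral of the normalized spectrum over one frequency band.
#' By default the integrand is the log2-normalized power (the quantity
#' plotted as "normalized EEG power"); set `prelog = TRUE` to integrate the
#' pre-log normalized power instead.
#'
#' @param ns a [normalize_spectrum()] result.
#' @param band a band name from [eeg_bands()] or a numeric `c(lo, hi)` within
#'   0.1-50 Hz.
#' @param prelog integrate pre-log normalized power instead of log2.
#' @return the AUC (unitless x Hz); 0 for a band containing fewer than two
#'   grid points.
#' @export
band_auc <- function(ns, band, prelog = FALSE) {
  if (is.character(band)) {
    bd <- eeg_bands()
    if (!band %in% bd$band) stop("unknown band: ", band)
    lims <- c(bd$lo[bd$band == band], bd$hi[bd$band == band])
  } else {
    lims <- as.numeric(band)
  }
  if (lims[1] < 0.1 || lims[2] > 50) stop("band outside the 0.1-50 Hz grid")
  sel <- ns$frequency >= lims[1] & ns$frequency <= lims[2]
  y <- if (prelog) attr(ns, "normalized_power")[sel] else ns$log2_power[sel]
  trapezoid(ns$frequency[sel], y)
}
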