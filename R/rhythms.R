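#' Cosinor fit of a rhythmic activity trace
#'
#' Least-squares sinusoidal regression
#' `y = M + b1 * cos(w t) + b2 * sin(w t)` with `w = 2 pi / period`, the
#' linearized form of `y = M + A cos(w (t - phi))`. The amplitude is
#' `sqrt(b1^2 + b2^2)` and the acrophase (time of peak relative to ZT0) is
#' `atan2(b2, b1) * period / (2 pi)`, wrapped into `[0, period)`. A constant
#' trace yields amplitude 0 with an undefined (NA) acrophase.
#'
#' @param trace data.frame with `zt_hours` and `activity` columns (e.g. from
#'   [gen_activity_trace()]); must span at least one period and contain at
#'   least 4 points.
#' @param period_h fitted period in hours (default 24).
#' @return object of class `cosinor_fit`: `mesor`, `amplitude`,
#'   `acrophase_h`, `period_h`, `r_squared`, `degenerate` (TRUE when the
#'   amplitude is numerically zero).
#' @export
cosinor_fit <- function(trace, period_h = 24) {
  t <- trace$zt_hours
  y <- trace$activity
  if (length(t) < 4) stop("need at least 4 points")
  if (diff(range(t)) < period_h - 1e-9) stop("trace must span at least one period")
  w <- 2 * pi / period_h
  fit <- stats::lm(y ~ cos(w * t) + sin(w * t))
  b <- stats::coef(fit)
  amplitude <- sqrt(b[2]^2 + b[3]^2)
  degenerate <- amplitude < 1e-10
  acrophase <- if (degenerate) NA_real_ else
    (atan2(b[3], b[2]) * period_h / (2 * pi)) %% period_h
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(
    mesor = unname(b[1]), amplitude = unname(amplitude),
    acrophase_h = unname(acrophase), period_h = period_h,
    r_squared = unname(r2), degenerate = degenerate
  ), class = "cosinor_fit")
}

# light phase is ZT0-12, dark ZT12-24
hyp_phase <- function(hyp) ifelse(hyp$zt_hours %% 24 < 12, "light", "dark")

#' Percentage of time asleep in a light phase
#'
#' Fraction of epochs scored NREM or REM among all epochs falling in the
#' requested phase (light = ZT0-12, dark = ZT12-24), as a percentage.
#'
#' @param hyp a [hypnogram()].
#' @param phase `"light"` or `"dark"`.
#' @return percentage in [0, 100].
#' @export
sleep_percent <- function(hyp, phase = c("light", "dark")) {
  phase <- match.arg(phase)
  in_phase <- hyp_phase(hyp) == phase
  if (!any(in_phase)) stop("no epochs fall in the ", phase, " phase")
  100 * mean(hyp$state[in_phase] %in% c("NREM", "REM"))
}

#' Bout statistics per vigilance state
#'
#' A bout is a maximal run of identical state labels. Returns, per state,
#' the bout count, bouts per 24 h of record, mean bout duration and total
#' time. With `by_phase = TRUE` bouts are split at the ZT12 light/dark
#' boundary (a bout crossing the boundary counts once in each phase, with the
#' durations split), and bouts-per-day is normalized by the time spent in
#' that phase.
#'
#' @param hyp a [hypnogram()].
#' @param by_phase split by light/dark phase.
#' @return data.frame: `state` (+ `phase`), `n_bouts`, `bouts_per_day`,
#'   `mean_bout_s`, `total_s`.
#' @export
bout_stats <- function(hyp, by_phase = FALSE) {
  if (nrow(hyp) == 0) stop("empty hypnogram")
  epoch_s <- attr(hyp, "epoch_s")
  states <- c("Wake", "NREM", "REM")
  segment_stats <- function(labels, hours_per_day_base) {
    r <- rle(labels)
    do.call(rbind, lapply(states, function(st) {
      sel <- r$values == st
      n_b <- sum(sel)
      data.frame(
        state = st, n_bouts = n_b,
        bouts_per_day = n_b / hours_per_day_base * 24,
        mean_bout_s = if (n_b) mean(r$lengths[sel]) * epoch_s else 0,
        total_s = sum(r$lengths[sel]) * epoch_s,
        stringsAsFactors = FALSE
      )
    }))
  }
  if (!by_phase) {
    out <- segment_stats(hyp$state, nrow(hyp) * epoch_s / 3600)
    rownames(out) <- NULL
    return(out)
  }
  phase <- hyp_phase(hyp)
  out <- do.call(rbind, lapply(c("light", "dark"), function(ph) {
    sel <- phase == ph
    if (!any(sel)) return(NULL)
    # runs computed on state-within-phase segments: a run is broken wherever
    # the phase changes, which splits boundary-crossing bouts
    seg_id <- cumsum(c(TRUE, diff(which(sel)) > 1))
    labels <- hyp$state[sel]
    r_input <- paste0(seg_id, "|", labels)
    r <- rle(r_input)
    vals <- sub("^[0-9]+\\|", "", r$values)
    st_out <- do.call(rbind, lapply(states, function(st) {
      ss <- vals == st
      n_b <- sum(ss)
      data.frame(
        state = st, phase = ph, n_bouts = n_b,
        bouts_per_day = n_b / (sum(sel) * epoch_s / 3600) * 24,
        mean_bout_s = if (n_b) mean(r$lengths[ss]) * epoch_s else 0,
        total_s = sum(r$lengths[ss]) * epoch_s,
        stringsAsFactors = FALSE
      )
    }))
    st_out
  }))
  rownames(out) <- NULL
  out
}

#' State-transition counts
#'
#' Counts label changes between consecutive epochs, keyed by the ordered pair
#' using short state codes (W, N, R). The five transitions observed in intact
#' sleep architecture (W-N, N-R, N-W, R-N, R-W) are always reported (zeros
#' included); any other observed pair is appended. The total equals the number
#' of bouts minus one.
#'
#' @param hyp a [hypnogram()].
#' @return named integer vector of transition counts.
#' @export
transition_counts <- function(hyp) {
  if (nrow(hyp) == 0) stop("empty hypnogram")
  code <- c(Wake = "W", NREM = "N", REM = "R")
  runs <- rle(hyp$state)$values
  canonical <- c("W-N", "N-R", "N-W", "R-N", "R-W")
  counts <- stats::setNames(integer(length(canonical)), canonical)
  if (length(runs) >= 2) {
    pairs <- paste0(code[runs[-length(runs)]], "-", code[runs[-1]])
    tab <- table(pairs)
    extra <- setdiff(names(tab), canonical)
    counts[intersect(names(tab), canonical)] <-
      as.integer(tab[intersect(names(tab), canonical)])
    if (length(extra)) {
      counts <- c(counts, stats::setNames(as.integer(tab[extra]), extra))
    }
  }
  counts
}
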