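#' Default analysis configuration
#'
#' All tunables of the analysis pipeline in one nested list, overridable from
#' a YAML file via [load_config()]. Keys: `smooth$default_window` (pre-smoothing,
#' samples), `filter$windows` (filter-bank widths per setting), `cycle$bpm_range`
#' (physiologic heart-rate window for period search), `cycle$min_confidence`
#' (autocorrelation acceptance threshold), `cycle$onset_band` (near-zero
#' acceleration band, fraction of window max), `events$rho` (extremum
#' prominence floor), `events$zero_band` (crossing/touch band), `template`
#' (see [default_event_template()]) and `quality` thresholds.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    smooth = list(default_window = 3L),
    filter = list(windows = c(3L, 5L, 7L, 9L)),
    cycle = list(bpm_range = c(80, 220), min_confidence = 0.5,
                 onset_band = 0.1),
    events = list(rho = 0.15, zero_band = 0.05),
    template = list(prior_fractions = c(0, 0.15, 0.20, 0.55, 0.60, 0.85),
                    tolerance = 0.08),
    quality = list(flatness_score1 = 0.7, prominence_score2 = 0.25,
                   biphasic_window = 0.05, biphasic_rel = 0.35,
                   biphasic_guard_samples = 1.5, biphasic_min = 2L)
  )
}

#' Load a YAML configuration, merged over the defaults
#'
#' @param path path to a YAML file mirroring the [default_config()] layout;
#'   missing keys keep their defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

tdi_condition <- function(reason, msg) {
  structure(class = c(paste0("fetaltdi_", reason), "fetaltdi_failure",
                      "error", "condition"),
            list(message = msg, call = NULL, reason = reason))
}

#' Estimate the cardiac period without an ECG
#'
#' Autocorrelation of the mean-removed velocity trace, searched over lags
#' corresponding to the physiologic heart-rate window (default 80-220 bpm).
#' The period is the lag of the highest autocorrelation value in that window
#' and the confidence is that (normalized) value; below the confidence
#' threshold the trace is declared non-periodic.
#'
#' @param trace a [velocity_trace()], spanning at least two expected cycles
#'   (>= 0.6 s at fetal rates).
#' @param bpm_range heart-rate search window, beats/min.
#' @param min_confidence minimum normalized autocorrelation (default 0.5).
#' @return list with `period` (s), `confidence` (0-1), `lag` (samples).
#' @export
estimate_period <- function(trace, bpm_range = c(80, 220),
                            min_confidence = 0.5) {
  stopifnot(inherits(trace, "velocity_trace"))
  v <- trace$samples
  n <- length(v)
  r <- trace$sampling_rate
  if (n / r < 0.6)
    stop(tdi_condition("no_periodicity",
                       "trace too short to span two cardiac cycles"))
  if (stats::sd(v) < 1e-12)
    stop(tdi_condition("no_periodicity", "constant trace has no periodicity"))
  lag_min <- max(2L, floor(r * 60 / bpm_range[2L]))
  lag_max <- min(n - 2L, ceiling(r * 60 / bpm_range[1L]))
  if (lag_max <= lag_min)
    stop(tdi_condition("no_periodicity",
                       "trace too short for the physiologic lag window"))
  v <- v - mean(v)
  ac <- stats::acf(v, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  idx <- (lag_min:lag_max) + 1L          # acf[1] is lag 0
  best <- which.max(ac[idx])
  lag <- lag_min + best - 1L
  conf <- ac[idx][best]
  if (!is.finite(conf) || conf < min_confidence)
    stop(tdi_condition("no_periodicity",
                       sprintf("no periodicity: best autocorrelation %.2f below %.2f",
                               conf, min_confidence)))
  # Sub-sample refinement: parabola through the acf peak and its neighbors.
  lag_ref <- lag
  if (lag > lag_min && lag < lag_max) {
    y0 <- ac[lag]; y1 <- ac[lag + 1L]; y2 <- ac[lag + 2L]
    den <- y0 - 2 * y1 + y2
    if (abs(den) > 1e-12) {
      d <- 0.5 * (y0 - y2) / den
      if (abs(d) <= 0.5) lag_ref <- lag + d
    }
  }
  list(period = lag_ref / r, confidence = conf, lag = lag)
}

#' Locate atrial-contraction onsets (cycle starts)
#'
#' The cardiac cycle starts at atrial contraction, when the AV-plane first
#' moves after diastasis. Candidate onsets are the points where acceleration
#' departs downward from a near-zero band (|a| below `onset_band` x the
#' window maximum) heading into the A-wave. Each candidate is scored by the
#' quietness of the velocity just before it (true atrial onsets follow the
#' diastasis lull); the quietest candidate anchors a chain that is extended
#' forward and backward in steps of one period (candidates accepted within
#' +/- 20 % of the period). Only onsets that begin a complete cycle are
#' returned.
#'
#' @param trace smoothed [velocity_trace()] in canonical orientation.
#' @param acc matching [acceleration_trace()].
#' @param period cardiac period in seconds (from [estimate_period()]).
#' @param onset_band near-zero band as a fraction of max |a| (default 0.1).
#' @return numeric vector of onset times in seconds, strictly increasing.
#' @export
locate_cycle_starts <- function(trace, acc, period, onset_band = 0.1) {
  stopifnot(inherits(trace, "velocity_trace"),
            inherits(acc, "acceleration_trace"))
  a <- acc$samples
  v <- trace$samples
  n <- length(a)
  r <- trace$sampling_rate
  if (n / r < period)
    stop(tdi_condition("insufficient_shifts",
                       "trace shorter than one cardiac period"))
  M <- max(abs(a))
  if (M <= 0)
    stop(tdi_condition("insufficient_shifts", "acceleration identically zero"))
  thr <- onset_band * M
  # Downward band departures: a drops below -thr after being above it. A
  # trace that begins mid-departure counts as departing at its first sample.
  dep <- which(a[-1L] < -thr & a[-n] >= -thr) + 1L
  if (a[1L] < -thr) dep <- c(1L, dep)
  if (length(dep) == 0L)
    stop(tdi_condition("insufficient_shifts",
                       "no downward acceleration departures found"))
  # Quietness of the velocity in the 12 % of a period preceding each
  # candidate; atrial onsets follow the diastasis lull.
  qwin <- max(2L, round(0.12 * period * r))
  vamp <- stats::quantile(abs(v - stats::median(v)), 0.95, names = FALSE)
  quiet <- vapply(dep, function(i) {
    lo <- max(1L, i - qwin)
    if (lo >= i) return(1)
    mean(abs(v[lo:(i - 1L)] - stats::median(v))) / max(vamp, 1e-12)
  }, 0)
  quiet <- pmin(quiet, 1)
  # Penalize candidates whose preceding window is clipped by the trace edge.
  quiet[dep <= qwin %/% 2L] <- quiet[dep <= qwin %/% 2L] + 0.05
  anchor <- dep[which.min(quiet)]
  plag <- period * r
  tolr <- 0.2 * plag
  chain <- anchor
  repeat {                               # forward
    target <- chain[length(chain)] + plag
    ok <- dep[abs(dep - target) <= tolr]
    if (length(ok) == 0L) {
      if (target > n) break
      # no candidate this beat: stop chaining rather than fabricate
      break
    }
    chain <- c(chain, ok[which.min(abs(ok - target) + 0.1 * tolr * quiet[match(ok, dep)])])
  }
  repeat {                               # backward
    target <- chain[1L] - plag
    ok <- dep[abs(dep - target) <= tolr]
    if (length(ok) == 0L) break
    chain <- c(ok[which.min(abs(ok - target) + 0.1 * tolr * quiet[match(ok, dep)])], chain)
  }
  # A chain head whose pre-onset window is clipped by the trace edge cannot
  # be verified against a preceding diastasis lull; drop it rather than risk
  # anchoring a cycle on a mid-phase departure.
  while (length(chain) > 1L && chain[1L] <= qwin) chain <- chain[-1L]
  # Refine each onset to the vertex of the jerk peak at the diastasis-to-
  # A-wave junction: the departure sample is biased by the smoothing
  # half-width, while the (symmetric) step midpoint - the jerk maximum -
  # sits at the true onset.
  jk <- c(0, abs(a[3:n] - a[1:(n - 2L)]) * r / 2, 0)
  refine <- function(i) {
    hw <- max(2L, round(0.03 * period * r))
    w <- max(2L, i - hw):min(n - 1L, i + hw)
    j <- w[which.max(jk[w])]
    den <- jk[j - 1L] - 2 * jk[j] + jk[j + 1L]
    d <- if (abs(den) > 1e-12) 0.5 * (jk[j - 1L] - jk[j + 1L]) / den else 0
    j + max(-0.5, min(0.5, d))
  }
  chain <- vapply(chain, refine, 0)
  # Keep only onsets that begin a complete cycle inside the trace.
  times <- trace$time_start + (chain - 1) / r
  t_end <- trace$time_start + (n - 1L) / r
  times <- times[times + period <= t_end + 0.5 / r]
  if (length(times) < 1L)
    stop(tdi_condition("insufficient_shifts",
                       "no complete cardiac cycle inside the trace"))
  times
}
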