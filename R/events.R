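#' Detect acceleration shifts in a time window
#'
#' Shifts in acceleration carry the timing information of the cardiac cycle:
#' phase onsets show up either as sign changes of the acceleration or as
#' places where it touches a near-zero band, and peak myocardial work shows
#' up as prominent local extrema. Three candidate sources are combined:
#'
#' * strict zero crossings - adjacent samples of opposite sign, both outside
#'   the near-zero band; the time is linearly interpolated;
#' * band events - maximal runs of samples with |a| below `zero_band` x the
#'   window maximum. A run whose flanks have opposite signs is a slow zero
#'   crossing (one candidate at its minimum); a run flanked by equal signs is
#'   a zero touch, and a long run is a silent interval (diastasis) - both
#'   yield candidates at the run's first and last samples, where the
#'   acceleration departs from zero;
#' * local extrema of the acceleration with |a| at least `rho` x the window
#'   maximum.
#'
#' @param acc an [acceleration_trace()].
#' @param window `c(start, end)` in seconds, inside the trace.
#' @param rho extremum prominence floor, fraction of window max |a|.
#' @param zero_band near-zero band, fraction of window max |a|.
#' @return data.frame with columns `time` (s), `index` (1-based sample index
#'   in `acc`), `kind` (`"zero_crossing"` or `"local_extremum"`), `magnitude`
#'   (|a| at an extremum, |slope| at a crossing) and `sign`, ordered by time.
#'   Empty when the window's acceleration is identically zero.
#' @export
detect_shifts <- function(acc, window, rho = 0.15, zero_band = 0.05) {
  stopifnot(inherits(acc, "acceleration_trace"), length(window) == 2L)
  tt <- trace_times(acc)
  sel <- which(tt >= window[1L] - 1e-9 & tt <= window[2L] + 1e-9)
  if (length(sel) < 3L)
    stop("detect_shifts: empty or too-narrow window", call. = FALSE)
  a <- acc$samples[sel]
  t <- tt[sel]
  n <- length(a)
  r <- acc$sampling_rate
  M <- max(abs(a))
  empty <- data.frame(time = numeric(0), index = integer(0),
                      kind = character(0), magnitude = numeric(0),
                      sign = numeric(0))
  if (M <= 0) return(empty)
  band <- zero_band * M
  out <- list()

  # Strict zero crossings (both samples outside the band).
  i <- which(a[-n] * a[-1L] < 0 & abs(a[-n]) >= band & abs(a[-1L]) >= band)
  if (length(i) > 0L) {
    frac <- a[i] / (a[i] - a[i + 1L])
    out[[length(out) + 1L]] <- data.frame(
      time = t[i] + frac / r,
      index = sel[ifelse(frac > 0.5, i + 1L, i)],
      kind = "zero_crossing",
      magnitude = abs(a[i + 1L] - a[i]) * r,
      sign = sign(a[i + 1L] - a[i]))
  }

  # Zero-intercept of the line through two flank samples (sub-sample
  # localization of where the acceleration reaches zero).
  flank_zero <- function(i1, i2) {
    if (abs(a[i2] - a[i1]) < 1e-12) return(NA_real_)
    t[i1] - a[i1] * (t[i2] - t[i1]) / (a[i2] - a[i1])
  }

  # Band runs: touches, slow crossings and silent intervals.
  inband <- abs(a) < band
  if (any(inband)) {
    rl <- rle(inband)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      s <- starts[k]; e <- ends[k]
      before <- if (s > 1L) sign(a[s - 1L]) else 0
      after <- if (e < n) sign(a[e + 1L]) else 0
      slow_cross <- before != 0 && after != 0 && before != after &&
        (e - s) < max(3L, round(0.01 * n))
      if (slow_cross) {
        j <- s + which.min(abs(a[s:e])) - 1L
        out[[length(out) + 1L]] <- data.frame(
          time = t[j], index = sel[j], kind = "zero_crossing",
          magnitude = abs(after - before) * band * r, sign = after)
      } else {
        # Candidates where the acceleration leaves/returns to zero; the
        # flank outside the run is extrapolated to its zero intercept for
        # sub-sample localization. The run's deepest point covers V-shaped
        # touches between same-sign lobes.
        jmin <- s + which.min(abs(a[s:e])) - 1L
        add <- function(tm, j, sg) {
          tm2 <- if (is.finite(tm)) max(t[max(j - 2L, 1L)],
                                        min(t[min(j + 2L, n)], tm)) else t[j]
          out[[length(out) + 1L]] <<- data.frame(
            time = tm2, index = sel[j], kind = "zero_crossing",
            magnitude = band * r, sign = sg)
        }
        if (s > 1L) add(if (s > 2L) flank_zero(s - 2L, s - 1L) else t[s],
                        s, -before)
        if (e < n) add(if (e < n - 1L) flank_zero(e + 2L, e + 1L) else t[e],
                       e, after)
        if (jmin != s && jmin != e) add(t[jmin], jmin, after)
      }
    }
  }

  # Prominent local extrema of the signed acceleration, refined to the
  # vertex of the parabola through the extremum and its neighbors.
  if (n >= 3L) {
    d1 <- diff(a)
    i <- which(d1[-(n - 1L)] * d1[-1L] < 0) + 1L
    i <- i[abs(a[i]) >= rho * M]
    if (length(i) > 0L) {
      den <- a[i - 1L] - 2 * a[i] + a[i + 1L]
      dt <- ifelse(abs(den) > 1e-12,
                   pmax(-0.5, pmin(0.5, 0.5 * (a[i - 1L] - a[i + 1L]) / den)),
                   0)
      out[[length(out) + 1L]] <- data.frame(
        time = t[i] + dt / r, index = sel[i], kind = "local_extremum",
        magnitude = abs(a[i]), sign = sign(a[i]))
    }
  }

  # Acceleration steps ("shifts" proper): abrupt changes of acceleration
  # level, located at prominent local extrema of the jerk |da/dt| and
  # refined to the jerk parabola vertex. A myocardial-work shift produces a
  # velocity-slope break, which is exactly such a step. A sharpness test
  # (the peak must dwarf the jerk a few samples away on at least one side)
  # rejects the smooth jerk undulations of sinusoid-like signals.
  if (n >= 9L) {
    jk <- c(0, (a[3:n] - a[1:(n - 2L)]) * r / 2, 0)
    ajk <- abs(jk)
    Mj <- max(ajk)
    if (Mj > 0) {
      dj <- diff(ajk)
      i <- which(dj[-(n - 1L)] * dj[-1L] < 0) + 1L
      i <- i[ajk[i] >= rho * Mj & i > 4L & i < n - 3L]
      i <- i[ajk[i] >= 1.25 * pmin(ajk[i - 4L], ajk[i + 4L])]
      if (length(i) > 0L) {
        den <- ajk[i - 1L] - 2 * ajk[i] + ajk[i + 1L]
        dt <- ifelse(abs(den) > 1e-12,
                     pmax(-0.5, pmin(0.5, 0.5 * (ajk[i - 1L] - ajk[i + 1L]) / den)),
                     0)
        out[[length(out) + 1L]] <- data.frame(
          time = t[i] + dt / r, index = sel[i], kind = "step",
          magnitude = ajk[i], sign = sign(jk[i]))
      }
    }
  }

  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$time), , drop = FALSE]
  res <- res[!duplicated(res[c("index", "kind")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Default event-matching template
#'
#' Expected onset positions of the six phases as fractions of the cycle,
#' matching the synthetic generator's default phase layout (cumulative sums
#' of the default phase fractions), with a +/- 0.08-cycle tolerance window
#' per event. Any shift kind is allowed for any event by default; both the
#' priors and the allowed kinds are configuration, enabling recalibration.
#'
#' @param prior_fractions 6 strictly increasing fractions in `[0, 1)`,
#'   first = 0.
#' @param tolerance half-width of each event's search window, cycle fraction
#'   (scalar or length 6).
#' @param required_kinds list of 6 character vectors of allowed shift kinds.
#' @return list of class `event_template`.
#' @export
default_event_template <- function(prior_fractions = c(0, 0.15, 0.20,
                                                       0.55, 0.60, 0.85),
                                   tolerance = 0.08,
                                   required_kinds = NULL) {
  prior_fractions <- as.numeric(prior_fractions)
  if (length(prior_fractions) != 6L || prior_fractions[1L] != 0 ||
      any(diff(prior_fractions) <= 0) || any(prior_fractions >= 1))
    stop("event_template: need 6 strictly increasing fractions in [0,1), first 0",
         call. = FALSE)
  tolerance <- rep_len(as.numeric(tolerance), 6L)
  if (any(tolerance <= 0))
    stop("event_template: tolerances must be positive", call. = FALSE)
  if (is.null(required_kinds))
    required_kinds <- rep(list(c("zero_crossing", "local_extremum", "step")), 6L)
  structure(list(prior_fractions = prior_fractions, tolerance = tolerance,
                 required_kinds = required_kinds),
            class = "event_template")
}

# Constrained least-squares assignment of candidates to events 2..6 by
# dynamic programming over time-ordered candidates: minimize the summed
# squared deviation of candidate cycle-fractions from the template priors,
# subject to strictly increasing times, per-event tolerance windows and
# allowed kinds. Returns chosen candidate row indices or NULL.
assign_events <- function(frac, kind, template) {
  m <- length(frac)
  cost <- matrix(Inf, nrow = 5L, ncol = m)
  for (e in 2:6) {
    ok <- abs(frac - template$prior_fractions[e]) <= template$tolerance[e] &
      kind %in% template$required_kinds[[e]] & frac > 0 & frac < 1
    cost[e - 1L, ok] <- (frac[ok] - template$prior_fractions[e])^2
  }
  dp <- matrix(Inf, nrow = 5L, ncol = m)
  back <- matrix(NA_integer_, nrow = 5L, ncol = m)
  dp[1L, ] <- cost[1L, ]
  eps <- 1e-12
  for (e in 2:5) {
    ptr <- 1L; best <- Inf; arg <- NA_integer_
    for (j in seq_len(m)) {
      while (ptr < j && frac[ptr] < frac[j] - eps) {
        if (dp[e - 1L, ptr] < best) { best <- dp[e - 1L, ptr]; arg <- ptr }
        ptr <- ptr + 1L
      }
      if (is.finite(cost[e, j]) && is.finite(best)) {
        dp[e, j] <- best + cost[e, j]
        back[e, j] <- arg
      }
    }
  }
  last <- which.min(dp[5L, ])
  if (!is.finite(dp[5L, last])) return(NULL)
  picks <- integer(5L)
  picks[5L] <- last
  for (e in 5:2) picks[e - 1L] <- back[e, picks[e]]
  picks
}

#' Segment one cardiac cycle into its six phases
#'
#' Assigns one acceleration-shift candidate to each of the six phase onsets.
#' The atrial-contraction onset is fixed to the cycle start; the remaining
#' five events are chosen among the candidates to minimize the summed squared
#' deviation of their cycle-fractions from the template priors, under strict
#' time ordering, per-event tolerance windows and allowed candidate kinds
#' (solved by dynamic programming over the time-ordered candidates).
#'
#' @param vel smoothed [velocity_trace()] (canonical orientation).
#' @param acc matching [acceleration_trace()].
#' @param cycle `c(onset, onset + period)` in seconds.
#' @param template an [default_event_template()].
#' @param rho,zero_band passed to [detect_shifts()].
#' @return a [phase_segmentation()].
#' @export
segment_cycle <- function(vel, acc, cycle, template = default_event_template(),
                          rho = 0.15, zero_band = 0.05) {
  stopifnot(length(cycle) == 2L, cycle[2L] > cycle[1L])
  cand <- detect_shifts(acc, cycle, rho = rho, zero_band = zero_band)
  if (nrow(cand) < 6L)
    stop(tdi_condition("insufficient_shifts",
                       sprintf("only %d shift candidates in cycle", nrow(cand))))
  period <- cycle[2L] - cycle[1L]
  frac <- (cand$time - cycle[1L]) / period
  picks <- assign_events(frac, cand$kind, template)
  if (is.null(picks))
    stop(tdi_condition("template_mismatch",
                       "no feasible candidate assignment matches the template"))
  onset_idx <- which.min(abs(trace_times(acc) - cycle[1L]))
  phase_segmentation(
    boundaries = c(cycle[1L], cand$time[picks]),
    cycle_end = cycle[2L],
    shift_indices = c(onset_idx, cand$index[picks]))
}

dominant_reason <- function(reasons) {
  if (length(reasons) == 0L) return("no_periodicity")
  tab <- table(factor(reasons, levels = FAILURE_REASONS))
  names(tab)[which.max(tab)]
}

#' Run the full automated analysis on one velocity trace
#'
#' The complete pipeline: pre-smooth with a 3-point moving average, then try
#' the four filter-bank settings in order. For each setting the trace is
#' filtered, differentiated, the cardiac period estimated by autocorrelation,
#' atrial onsets located, and every complete cycle segmented by template
#' matching over acceleration shifts. The first setting for which at least
#' half of the cycles (rounded up) segment successfully is accepted. Peak
#' velocities and phase durations are aggregated across the successful cycles
#' by median (robust to the odd bad beat), and the trace receives a 1-3
#' acceleration quality score. Failures never raise: they are encoded in the
#' result's `success`/`failure_reason`.
#'
#' @param trace a [velocity_trace()].
#' @param config configuration list (see [default_config()]).
#' @param invert flip trace polarity before analysis (opposite probe
#'   orientation).
#' @return an [analysis_result()].
#' @export
analyze_trace <- function(trace, config = default_config(), invert = FALSE) {
  stopifnot(inherits(trace, "velocity_trace"))
  fail <- function(reason)
    analysis_result(trace$label, success = FALSE, failure_reason = reason)
  if (length(trace$samples) < 8L || stats::sd(trace$samples) < 1e-12)
    return(fail("degenerate_input"))
  work <- trace
  if (invert) work$samples <- -work$samples
  work <- moving_average(work, config$smooth$default_window)
  template <- default_event_template(config$template$prior_fractions,
                                     config$template$tolerance)
  reasons <- character(0)
  for (setting in seq_along(config$filter$windows)) {
    filt <- try(filter_bank(work, setting, config$filter$windows), silent = TRUE)
    if (inherits(filt, "try-error")) { reasons <- c(reasons, "degenerate_input"); next }
    acc <- acceleration(filt)
    pe <- tryCatch(estimate_period(filt, config$cycle$bpm_range,
                                   config$cycle$min_confidence),
                   fetaltdi_failure = function(e) e)
    if (inherits(pe, "condition")) { reasons <- c(reasons, pe$reason); next }
    onsets <- tryCatch(locate_cycle_starts(filt, acc, pe$period,
                                           config$cycle$onset_band),
                       fetaltdi_failure = function(e) e)
    if (inherits(onsets, "condition")) { reasons <- c(reasons, onsets$reason); next }
    segs <- list(); cyc_fail <- character(0)
    for (on in onsets) {
      sg <- tryCatch(segment_cycle(filt, acc, c(on, on + pe$period), template,
                                   rho = config$events$rho,
                                   zero_band = config$events$zero_band),
                     fetaltdi_failure = function(e) e)
      if (inherits(sg, "condition")) cyc_fail <- c(cyc_fail, sg$reason)
      else segs[[length(segs) + 1L]] <- sg
    }
    need <- ceiling(length(onsets) / 2)
    if (length(segs) >= max(1L, need)) {
      # amplitudes from the minimally smoothed trace: the stronger filter
      # settings are for timing only and would attenuate the narrow A-wave
      pvs <- lapply(segs, function(s) peak_velocities(work, s))
      ivs <- lapply(segs, function(s) interval_durations(s)$durations)
      pv <- list(sm = stats::median(vapply(pvs, `[[`, 0, "sm")),
                 em = stats::median(vapply(pvs, `[[`, 0, "em")),
                 am = stats::median(vapply(pvs, `[[`, 0, "am")))
      dmat <- do.call(rbind, ivs)
      iv <- structure(list(durations = apply(dmat, 2L, stats::median)),
                      class = "interval_set")
      qs <- acceleration_score(acc, segs[[1L]], config = config)
      res <- analysis_result(trace$label, success = TRUE,
                             segmentations = segs, peak_velocities = pv,
                             intervals = iv,
                             acceleration_score = qs$score,
                             filter_setting_used = setting)
      # per-cycle detail kept out of the serialized result
      attr(res, "cycle_peaks") <- pvs
      attr(res, "quality") <- qs
      return(res)
    }
    reasons <- c(reasons, if (length(cyc_fail) > 0L) cyc_fail else "template_mismatch")
  }
  fail(dominant_reason(reasons))
}

#' Analyze a batch of traces
#'
#' @param traces list of [velocity_trace()].
#' @param config configuration list.
#' @param invert polarity flag applied to every trace.
#' @return list of [analysis_result()].
#' @export
analyze_traces <- function(traces, config = default_config(), invert = FALSE) {
  lapply(traces, analyze_trace, config = config, invert = invert)
}
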