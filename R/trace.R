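#' Construct a myocardial velocity trace
#'
#' A `velocity_trace` is a uniformly sampled longitudinal myocardial velocity
#' signal for one wall / ROI, the basic unit of analysis. Sample `i` (0-based)
#' is located at `time_start + i / sampling_rate`. Velocities are in cm/s with
#' the canonical sign convention: positive toward the apex/transducer during
#' systole, so Sm > 0 and Em, Am < 0. Opposite probe orientation is handled by
#' the `invert` argument of [analyze_trace()].
#'
#' @param samples numeric vector of velocities in cm/s, length >= 2, all finite.
#' @param sampling_rate sampling frequency in Hz (> 0). Color-TDI cine loops in
#'   fetal work typically run near 190 frames/s.
#' @param time_start time of the first sample in seconds (default 0).
#' @param label wall identifier: `"septum"`, `"left_wall"`, `"right_wall"` or
#'   any other string for unspecified walls.
#' @param roi optional [roi_spec()] describing the sampling region.
#' @return An object of class `velocity_trace`.
#' @examples
#' tr <- velocity_trace(sin(2 * pi * 2.3 * seq(0, 2, by = 1 / 190)), 190)
#' trace_times(tr)[1:3]
#' @export
velocity_trace <- function(samples, sampling_rate, time_start = 0,
                           label = "other", roi = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("velocity_trace: need at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("velocity_trace: all samples must be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("velocity_trace: sampling_rate must be a positive number", call. = FALSE)
  if (!is.null(roi)) stopifnot(inherits(roi, "roi_spec"))
  structure(
    list(label = as.character(label)[1L],
         time_start = as.numeric(time_start)[1L],
         sampling_rate = as.numeric(sampling_rate),
         samples = samples,
         roi = roi),
    class = "velocity_trace")
}

#' Construct an acceleration trace
#'
#' Same layout as [velocity_trace()] but values are in cm/s^2 and the object
#' remembers which velocity trace it was derived from. Produced by
#' [acceleration()]; rarely constructed by hand.
#'
#' @param samples numeric vector of accelerations in cm/s^2.
#' @param sampling_rate sampling frequency in Hz.
#' @param time_start time of the first sample in seconds.
#' @param source_trace_label label of the velocity trace this derives from.
#' @return An object of class `acceleration_trace`.
#' @export
acceleration_trace <- function(samples, sampling_rate, time_start = 0,
                               source_trace_label = "other") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("acceleration_trace: need at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("acceleration_trace: all samples must be finite", call. = FALSE)
  if (sampling_rate <= 0)
    stop("acceleration_trace: sampling_rate must be positive", call. = FALSE)
  structure(
    list(source_trace_label = as.character(source_trace_label)[1L],
         time_start = as.numeric(time_start)[1L],
         sampling_rate = as.numeric(sampling_rate),
         samples = samples),
    class = "acceleration_trace")
}

#' Sample times of a trace
#'
#' @param trace a `velocity_trace` or `acceleration_trace`.
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$time_start + (seq_along(trace$samples) - 1L) / trace$sampling_rate
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace '%s'> %d samples @ %.6g Hz (%.3f s)\n",
              x$label, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (!is.null(x$roi))
    cat(sprintf("  ROI %g x %g mm, center %g mm below AV-plane\n",
                x$roi$height_mm, x$roi$width_mm, x$roi$center_offset_mm))
  invisible(x)
}

#' @export
print.acceleration_trace <- function(x, ...) {
  cat(sprintf("<acceleration_trace from '%s'> %d samples @ %.6g Hz\n",
              x$source_trace_label, length(x$samples), x$sampling_rate))
  invisible(x)
}

#' Specify a region of interest
#'
#' An ROI is a fixed (stationary) rectangular sampling window placed at the
#' level of the atrioventricular plane in a myocardial wall. `height_mm` runs
#' along the wall (the direction of AV-plane motion), `width_mm` across it.
#' The ROI must lie entirely below the AV-plane, so its center sits at least
#' half its height down the wall; the default placement puts the top edge
#' exactly at the AV-plane.
#'
#' @param height_mm ROI length along the wall in mm (> 0).
#' @param width_mm ROI width across the wall in mm (> 0).
#' @param center_offset_mm distance of the ROI center below the AV-plane, in
#'   mm. Defaults to `height_mm / 2` (top edge at the AV-plane).
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec(2, 2)            # the 2 x 2 mm reference ROI
#' roi_spec(6, 4)            # a larger ROI for late gestation
#' @export
roi_spec <- function(height_mm, width_mm, center_offset_mm = height_mm / 2) {
  if (!is.finite(height_mm) || height_mm <= 0)
    stop("roi_spec: height_mm must be > 0", call. = FALSE)
  if (!is.finite(width_mm) || width_mm <= 0)
    stop("roi_spec: width_mm must be > 0", call. = FALSE)
  if (!is.finite(center_offset_mm) || center_offset_mm < height_mm / 2)
    stop("roi_spec: center_offset_mm must be >= height_mm / 2 (ROI fully below the AV-plane)",
         call. = FALSE)
  structure(list(height_mm = height_mm, width_mm = width_mm,
                 center_offset_mm = center_offset_mm),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %g x %g mm (height x width), center %g mm below AV-plane\n",
              x$height_mm, x$width_mm, x$center_offset_mm))
  invisible(x)
}

# Canonical order of the six cardiac phases, starting (per the piston-pump
# view of the heart) at atrial contraction.
PHASE_NAMES <- c("atrial_contraction", "pre_ejection", "ejection",
                 "post_ejection", "rapid_filling", "slow_filling")

#' The six cardiac phase names in cycle order
#'
#' The cardiac cycle is divided into atrial contraction, pre-ejection,
#' ventricular ejection, post-ejection, rapid filling and slow filling
#' (diastasis). Atrial contraction is the starting point of the cycle, and
#' pre-/post-ejection denote the transitions flanking ejection, defined by
#' shifts in myocardial work rather than valve events.
#'
#' @return character vector of length 6.
#' @export
phase_names <- function() PHASE_NAMES

#' Gestational-age group lookup
#'
#' Three gestational-age strata govern heart geometry and recommended ROI
#' size: GA I (18-24 weeks), GA II (25-32 weeks), GA III (33-41 weeks).
#'
#' @param ga_weeks gestational age in completed weeks (18-41).
#' @return list with `name` (`"GA_I"`, `"GA_II"` or `"GA_III"`) and
#'   `week_range` (inclusive `[low, high]`).
#' @examples
#' ga_group(21)$name   # "GA_I"
#' ga_group(38)$name   # "GA_III"
#' @export
ga_group <- function(ga_weeks) {
  if (!is.finite(ga_weeks) || ga_weeks < 18 || ga_weeks > 41)
    stop("ga_group: gestational age must be within 18-41 weeks", call. = FALSE)
  if (ga_weeks <= 24)      list(name = "GA_I",   week_range = c(18L, 24L))
  else if (ga_weeks <= 32) list(name = "GA_II",  week_range = c(25L, 32L))
  else                     list(name = "GA_III", week_range = c(33L, 41L))
}

#' Construct a six-phase segmentation of one cardiac cycle
#'
#' Holds the onsets of the six phases for one cycle plus the end of the cycle
#' (the next atrial-contraction onset). Phases are half-open intervals
#' `[onset, next onset)`, so the six phase durations sum exactly to the cycle
#' length. `shift_indices` records which acceleration-shift samples produced
#' each boundary (provenance; `NA` where a boundary was fixed by construction).
#'
#' @param boundaries numeric vector of 6 strictly increasing onset times in
#'   seconds, ordered as [phase_names()]; `boundaries[1]` is the cycle start.
#' @param cycle_end end of the cycle in seconds (> `boundaries[6]`).
#' @param shift_indices integer vector of 6 sample indices (1-based, `NA`
#'   allowed) of the acceleration shifts used.
#' @return An object of class `phase_segmentation`.
#' @export
phase_segmentation <- function(boundaries, cycle_end,
                               shift_indices = rep(NA_integer_, 6L)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 6L)
    stop("phase_segmentation: need exactly 6 boundaries", call. = FALSE)
  if (any(diff(boundaries) <= 0))
    stop("phase_segmentation: boundaries must be strictly increasing", call. = FALSE)
  if (!is.finite(cycle_end) || cycle_end <= boundaries[6L])
    stop("phase_segmentation: cycle_end must exceed the last boundary", call. = FALSE)
  names(boundaries) <- PHASE_NAMES
  structure(
    list(cycle_start = boundaries[[1L]],
         boundaries = boundaries,
         cycle_end = as.numeric(cycle_end),
         shift_indices = as.integer(shift_indices)),
    class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> cycle %.4f - %.4f s\n",
              x$cycle_start, x$cycle_end))
  d <- interval_durations(x)
  for (ph in PHASE_NAMES)
    cat(sprintf("  %-18s onset %.4f s  (%.1f ms)\n", ph, x$boundaries[[ph]],
                d$durations[[ph]]))
  invisible(x)
}

FAILURE_REASONS <- c("no_periodicity", "insufficient_shifts",
                     "template_mismatch", "degenerate_input")

#' Construct a per-trace analysis result
#'
#' Outcome of [analyze_trace()] for one velocity trace: success flag, the
#' per-cycle segmentations, peak velocities and interval durations aggregated
#' across cycles by median, the 1-3 acceleration quality score, and which of
#' the four filter settings produced the accepted segmentation.
#'
#' @param trace_label wall identifier of the analyzed trace.
#' @param success logical analyzability flag.
#' @param failure_reason one of `"no_periodicity"`, `"insufficient_shifts"`,
#'   `"template_mismatch"`, `"degenerate_input"`, or `NULL` on success.
#' @param segmentations list of [phase_segmentation()] (empty on failure).
#' @param peak_velocities list with `sm`, `em`, `am` in cm/s, or `NULL`.
#' @param intervals [interval_durations()] result (ms), or `NULL`.
#' @param acceleration_score integer quality grade 1-3, or `NA`.
#' @param filter_setting_used filter-bank setting 1-4, or `NA`.
#' @return An object of class `analysis_result`.
#' @export
analysis_result <- function(trace_label, success, failure_reason = NULL,
                            segmentations = list(), peak_velocities = NULL,
                            intervals = NULL, acceleration_score = NA_integer_,
                            filter_setting_used = NA_integer_) {
  success <- isTRUE(success)
  if (!success) {
    if (is.null(failure_reason) || !failure_reason %in% FAILURE_REASONS)
      stop("analysis_result: failed results need a valid failure_reason",
           call. = FALSE)
    if (length(segmentations) > 0L)
      stop("analysis_result: failed results must carry no segmentations",
           call. = FALSE)
  }
  structure(
    list(trace_label = as.character(trace_label)[1L],
         success = success,
         failure_reason = if (success) NULL else failure_reason,
         segmentations = segmentations,
         peak_velocities = peak_velocities,
         intervals = intervals,
         acceleration_score = as.integer(acceleration_score),
         filter_setting_used = as.integer(filter_setting_used)),
    class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("<analysis_result '%s'> %s\n", x$trace_label,
              if (x$success) "success" else paste0("FAILED (", x$failure_reason, ")")))
  if (x$success) {
    cat(sprintf("  %d cycles, filter setting %d, acceleration score %d\n",
                length(x$segmentations), x$filter_setting_used,
                x$acceleration_score))
    pv <- x$peak_velocities
    cat(sprintf("  Sm %.2f  Em %.2f  Am %.2f cm/s (medians across cycles)\n",
                pv$sm, pv$em, pv$am))
  }
  invisible(x)
}
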