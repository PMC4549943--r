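#' Extract peak myocardial velocities from a segmented cycle
#'
#' Sm is the maximum velocity during ventricular ejection, Em the minimum
#' during rapid filling (early diastole) and Am the minimum during atrial
#' contraction, under the canonical sign convention (systolic motion
#' positive). Phase windows are half-open `[onset, next onset)`.
#'
#' @param vel a [velocity_trace()].
#' @param seg a [phase_segmentation()] lying inside the trace.
#' @return list of class `peak_velocities` with `sm`, `em`, `am` (cm/s) and
#'   `times` (when each peak occurred, s).
#' @export
peak_velocities <- function(vel, seg) {
  stopifnot(inherits(vel, "velocity_trace"),
            inherits(seg, "phase_segmentation"))
  tt <- trace_times(vel)
  b <- seg$boundaries
  win <- function(from, to) {
    i <- which(tt >= from - 1e-9 & tt < to - 1e-9)
    if (length(i) == 0L)
      stop("peak_velocities: empty phase window", call. = FALSE)
    i
  }
  i_ej <- win(b[["ejection"]], b[["post_ejection"]])
  i_rf <- win(b[["rapid_filling"]], b[["slow_filling"]])
  i_ac <- win(b[["atrial_contraction"]], b[["pre_ejection"]])
  sm_i <- i_ej[which.max(vel$samples[i_ej])]
  em_i <- i_rf[which.min(vel$samples[i_rf])]
  am_i <- i_ac[which.min(vel$samples[i_ac])]
  structure(list(sm = vel$samples[sm_i], em = vel$samples[em_i],
                 am = vel$samples[am_i],
                 times = c(sm = tt[sm_i], em = tt[em_i], am = tt[am_i])),
            class = "peak_velocities")
}

#' Phase durations of a segmented cycle
#'
#' Successive onset differences, the last phase closed by the cycle end, in
#' milliseconds. By construction the six durations sum exactly to the cycle
#' length.
#'
#' @param seg a [phase_segmentation()].
#' @return list of class `interval_set` with `durations` (named, ms).
#' @export
interval_durations <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  d <- diff(c(seg$boundaries, cycle_end = seg$cycle_end)) * 1000
  names(d) <- PHASE_NAMES
  structure(list(durations = d), class = "interval_set")
}

#' Percent change relative to a reference measurement
#'
#' `100 * (value - reference) / reference`. For velocities the convention is
#' to compare magnitudes (`use_magnitude = TRUE`), so that attenuation of a
#' negative diastolic peak still reports a negative percent difference.
#'
#' @param value measurement(s).
#' @param reference reference measurement(s); must be nonzero.
#' @param use_magnitude compare `|value|` against `|reference|`.
#' @return percent difference(s), sign preserved.
#' @examples
#' percent_difference(4.5, 5.0)                       # -10
#' percent_difference(-4.2, -6.0, use_magnitude = TRUE) # -30
#' @export
percent_difference <- function(value, reference, use_magnitude = FALSE) {
  if (any(reference == 0))
    stop("percent_difference: zero reference", call. = FALSE)
  if (use_magnitude) {
    value <- abs(value); reference <- abs(reference)
    if (any(reference == 0))
      stop("percent_difference: zero reference", call. = FALSE)
  }
  100 * (value - reference) / reference
}

#' Median (IQR) summary of percent differences
#'
#' The reporting format of ROI-comparison tables: median percent difference
#' with the interquartile range (Q3 - Q1), quantiles by linear interpolation
#' (type 7).
#'
#' @param values numeric vector of percent differences (>= 1 value).
#' @param metric metric name (e.g. `"sm"`).
#' @param roi optional [roi_spec()] the differences refer to.
#' @param type quantile type (default 7, linear interpolation).
#' @return list of class `difference_summary` with `metric`, `roi`,
#'   `median_pct`, `iqr_pct`.
#' @export
summarize_differences <- function(values, metric = "metric", roi = NULL,
                                  type = 7) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("summarize_differences: empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  structure(list(metric = metric, roi = roi,
                 median_pct = q[2L], iqr_pct = q[3L] - q[1L]),
            class = "difference_summary")
}

# Round half away from zero (printed clinical tables round 0.5 up, not to
# even as R's round() does).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Feasibility summary of a batch of analyses
#'
#' Counts analyzable traces per wall and pooled, with percentages rounded to
#' the nearest integer (half away from zero). Accepts either a list of
#' [analysis_result()] (walls taken from `trace_label`) or a data.frame with
#' columns `wall`, `n_success`, `n_total`.
#'
#' @param results list of [analysis_result()] or a counts data.frame.
#' @return list of class `feasibility_summary` with `per_wall` (data.frame
#'   `wall`, `n_success`, `n_total`, `pct`) and `overall`.
#' @examples
#' feasibility(data.frame(wall = "right_wall", n_success = 81, n_total = 87))
#' @export
feasibility <- function(results) {
  if (is.data.frame(results)) {
    stopifnot(all(c("wall", "n_success", "n_total") %in% names(results)),
              nrow(results) > 0L)
    per <- results[c("wall", "n_success", "n_total")]
  } else {
    stopifnot(length(results) > 0L)
    wall <- vapply(results, `[[`, "", "trace_label")
    succ <- vapply(results, `[[`, TRUE, "success")
    per <- do.call(rbind, lapply(split(succ, wall), function(s)
      data.frame(n_success = sum(s), n_total = length(s))))
    per <- data.frame(wall = rownames(per), per, row.names = NULL)
  }
  if (any(per$n_success > per$n_total))
    stop("feasibility: n_success exceeds n_total", call. = FALSE)
  per$pct <- round_half_away(100 * per$n_success / per$n_total)
  ov <- data.frame(n_success = sum(per$n_success), n_total = sum(per$n_total))
  ov$pct <- round_half_away(100 * ov$n_success / ov$n_total)
  structure(list(per_wall = per, overall = ov), class = "feasibility_summary")
}

#' @export
print.feasibility_summary <- function(x, ...) {
  cat("<feasibility_summary>\n")
  for (i in seq_len(nrow(x$per_wall)))
    cat(sprintf("  %-12s %d %% (%d/%d)\n", x$per_wall$wall[i],
                x$per_wall$pct[i], x$per_wall$n_success[i],
                x$per_wall$n_total[i]))
  cat(sprintf("  %-12s %d %% (%d/%d)\n", "overall", x$overall$pct,
              x$overall$n_success, x$overall$n_total))
  invisible(x)
}

#' ROI length as a percentage of septal length
#'
#' The ROI height (along-wall length) expressed as an integer percentage of
#' the septal AV-plane-to-apex length, the standard way to compare ROI sizes
#' across gestations.
#'
#' @param roi_length_mm ROI height in mm (> 0).
#' @param septal_length_mm septal length in mm (> 0).
#' @return integer percent.
#' @examples
#' roi_fraction(2, 15.6)   # 13
#' roi_fraction(8, 32.5)   # 25
#' @export
roi_fraction <- function(roi_length_mm, septal_length_mm) {
  if (any(!is.finite(roi_length_mm)) || any(roi_length_mm <= 0) ||
      any(!is.finite(septal_length_mm)) || any(septal_length_mm <= 0))
    stop("roi_fraction: lengths must be positive", call. = FALSE)
  round_half_away(100 * roi_length_mm / septal_length_mm)
}

#' Recommended ROI size for a gestational age
#'
#' The recommended fixed ROI (height x width) balancing distinct acceleration
#' traces against loss of velocity information: 2 x 2 mm in GA I (18-24
#' weeks), 4 x 3 mm in GA II (25-32 weeks) and 6 x 4 mm in GA III (33-41
#' weeks).
#'
#' @param ga_weeks gestational age in weeks (18-41).
#' @return an [roi_spec()].
#' @examples
#' recommend_roi(20)   # 2 x 2 mm
#' recommend_roi(38)   # 6 x 4 mm
#' @export
recommend_roi <- function(ga_weeks) {
  switch(ga_group(ga_weeks)$name,
         GA_I   = roi_spec(2, 2),
         GA_II  = roi_spec(4, 3),
         GA_III = roi_spec(6, 4))
}

# ROI height (and group width) ladders used in the ROI-size study.
roi_ladder <- function(ga_group_name) {
  switch(ga_group_name,
         GA_I   = list(heights = c(2, 3, 4),       width = 2),
         GA_II  = list(heights = c(2, 3, 4, 6),    width = 3),
         GA_III = list(heights = c(2, 3, 4, 6, 8), width = 4))
}

#' ROI-size effect study on a synthetic velocity field
#'
#' Generates one synthetic field for the given gestational age, samples it
#' with the gestation-appropriate ladder of ROI heights (reference 2 mm),
#' analyzes every trace, and summarizes per-cycle percent differences of the
#' peak velocities (on magnitudes) and phase durations relative to the 2 mm
#' reference ROI as median (IQR).
#'
#' @param ga_weeks gestational age in weeks.
#' @param seed integer seed for the field.
#' @param noise_sd noise level, cm/s (default 0: noise-free).
#' @param heights optional override of the ROI-height ladder, mm.
#' @param config analysis configuration.
#' @return data.frame with one row per (metric, ROI height): `metric`,
#'   `roi_height_mm`, `median_pct`, `iqr_pct`, `n_cycles`.
#' @export
roi_study <- function(ga_weeks, seed = 1L, noise_sd = 0, heights = NULL,
                      config = default_config()) {
  grp <- ga_group(ga_weeks)$name
  lad <- roi_ladder(grp)
  if (!is.null(heights)) lad$heights <- heights
  params <- heart_model_params(noise_sd = noise_sd, ga_weeks = ga_weeks)
  field <- generate_field(params, seed = seed)
  res <- lapply(lad$heights, function(h) {
    tr <- sample_roi(field, roi_spec(h, lad$width),
                     label = sprintf("h%gmm", h))
    analyze_trace(tr, config = config)
  })
  ref <- res[[which(lad$heights == min(lad$heights))]]
  if (!ref$success)
    stop("roi_study: reference ROI trace failed to analyze", call. = FALSE)
  metrics <- c("sm", "em", "am", PHASE_NAMES)
  out <- list()
  for (k in seq_along(lad$heights)) {
    h <- lad$heights[k]
    if (h == min(lad$heights)) next
    r <- res[[k]]
    if (!r$success) next
    ncy <- min(length(r$segmentations), length(ref$segmentations))
    for (m in metrics) {
      vals <- vapply(seq_len(ncy), function(cy) {
        if (m %in% c("sm", "em", "am")) {
          a <- peak_velocities_of(r, cy)[[m]]
          b <- peak_velocities_of(ref, cy)[[m]]
          percent_difference(a, b, use_magnitude = TRUE)
        } else {
          a <- interval_durations(r$segmentations[[cy]])$durations[[m]]
          b <- interval_durations(ref$segmentations[[cy]])$durations[[m]]
          percent_difference(a, b)
        }
      }, 0)
      s <- summarize_differences(vals, metric = m)
      out[[length(out) + 1L]] <- data.frame(
        metric = m, roi_height_mm = h, median_pct = s$median_pct,
        iqr_pct = s$iqr_pct, n_cycles = ncy)
    }
  }
  do.call(rbind, out)
}

# Peak velocities of cycle `cy` of a successful analysis result, from the
# per-cycle detail analyze_trace() attaches as an attribute.
peak_velocities_of <- function(result, cy) {
  cp <- attr(result, "cycle_peaks")
  if (is.null(cp))
    stop("peak_velocities_of: per-cycle peaks unavailable", call. = FALSE)
  cp[[cy]]
}
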