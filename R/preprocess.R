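#' Centered moving-average smoothing
#'
#' Unweighted centered moving average, the smoothing EchoPAC-style exports
#' apply (three points by default). Near the edges the window is truncated to
#' the available samples, so the output has the same length as the input and
#' no spurious endpoint transients are introduced near cycle boundaries.
#'
#' @param trace a [velocity_trace()].
#' @param window odd window length in samples (default 3).
#' @return smoothed [velocity_trace()].
#' @export
moving_average <- function(trace, window = 3L) {
  stopifnot(inherits(trace, "velocity_trace"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("moving_average: window must be a positive odd integer", call. = FALSE)
  if (window > length(trace$samples))
    stop("moving_average: window exceeds trace length", call. = FALSE)
  trace$samples <- moving_average_num(trace$samples, window)
  trace
}

# O(n) running mean with truncated edge windows.
moving_average_num <- function(x, window) {
  if (window == 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' The four-setting smoothing filter bank
#'
#' The automated analyzer tries four successively stronger filter settings.
#' The published account does not disclose the filters themselves; here
#' setting `k` is reconstructed as a centered moving average of width
#' `2k + 1` (3, 5, 7, 9 samples), which at ~190 Hz spans roughly 16-47 ms.
#' The widths are configurable (`filter.windows`), so the bank is swappable.
#'
#' @param trace a [velocity_trace()].
#' @param setting integer filter setting 1-4.
#' @param windows window widths per setting (default `c(3, 5, 7, 9)`).
#' @return filtered [velocity_trace()].
#' @export
filter_bank <- function(trace, setting, windows = c(3L, 5L, 7L, 9L)) {
  setting <- as.integer(setting)
  if (is.na(setting) || setting < 1L || setting > length(windows))
    stop(sprintf("filter_bank: setting must be in 1-%d", length(windows)),
         call. = FALSE)
  moving_average(trace, windows[setting])
}

#' Differentiate velocity into acceleration
#'
#' Central differences on interior samples, one-sided differences at the two
#' edges. The symmetric interior stencil has zero phase delay, so the timing
#' of acceleration shifts (the basis of all event detection) is unbiased.
#'
#' @param trace a [velocity_trace()] (length >= 3).
#' @return an [acceleration_trace()] on the same grid, cm/s^2.
#' @export
acceleration <- function(trace) {
  stopifnot(inherits(trace, "velocity_trace"))
  v <- trace$samples
  n <- length(v)
  if (n < 3L)
    stop("acceleration: need at least 3 samples", call. = FALSE)
  r <- trace$sampling_rate
  a <- numeric(n)
  a[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) * r / 2
  a[1L] <- (v[2L] - v[1L]) * r
  a[n] <- (v[n] - v[n - 1L]) * r
  acceleration_trace(a, sampling_rate = r, time_start = trace$time_start,
                     source_trace_label = trace$label)
}
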