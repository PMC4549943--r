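#' Read velocity traces from a delimited text table
#'
#' Trace tables are plain text with a header row: column 1 is time in seconds
#' (monotone, uniformly spaced), every further column one velocity trace in
#' cm/s, its header used as the wall label. Export dialects vary by locale, so
#' the delimiter and decimal mark are configurable. The sampling rate is
#' inferred from the median time step; files whose timestamps stray from that
#' uniform grid by more than 25 % of a step are rejected.
#'
#' @param path path to the trace table.
#' @param delimiter field separator (default `","`).
#' @param decimal decimal mark (default `"."`).
#' @return list of [velocity_trace()], one per velocity column.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("t,septum", "0,0.0", "0.005,1.0", "0.010,2.0"), f)
#' read_trace_table(f)[[1]]
#' @export
read_trace_table <- function(path, delimiter = ",", decimal = ".") {
  if (!file.exists(path))
    stop(sprintf("read_trace_table: file not found: %s", path), call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter, dec = decimal,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) < 2L)
    stop("read_trace_table: fewer than 2 data rows", call. = FALSE)
  if (ncol(tab) < 2L)
    stop("read_trace_table: need a time column plus at least one velocity column",
         call. = FALSE)
  tt <- as.numeric(tab[[1L]])
  if (any(!is.finite(tt)))
    stop("read_trace_table: non-numeric values in the time column", call. = FALSE)
  steps <- diff(tt)
  if (any(steps <= 0))
    stop("read_trace_table: time column is not strictly increasing", call. = FALSE)
  step <- stats::median(steps)
  if (any(abs(steps - step) > 0.25 * step))
    stop("read_trace_table: non-uniform sampling (time step deviates by > 25 % of the median step)",
         call. = FALSE)
  rate <- 1 / step
  lapply(names(tab)[-1L], function(lab) {
    v <- as.numeric(tab[[lab]])
    if (any(!is.finite(v)))
      stop(sprintf("read_trace_table: non-finite values in column '%s'", lab),
           call. = FALSE)
    velocity_trace(v, sampling_rate = rate, time_start = tt[1L], label = lab)
  })
}

#' Write velocity traces to a delimited text table
#'
#' Inverse of [read_trace_table()]: one time column (seconds) plus one column
#' per trace. All traces must share sampling rate, start time and length.
#'
#' @param traces a [velocity_trace()] or list of them.
#' @param path output file path.
#' @param delimiter field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path, delimiter = ",") {
  if (inherits(traces, "velocity_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  r0 <- traces[[1L]]
  for (tr in traces)
    if (length(tr$samples) != length(r0$samples) ||
        tr$sampling_rate != r0$sampling_rate || tr$time_start != r0$time_start)
      stop("write_trace_table: traces must share grid (rate, start, length)",
           call. = FALSE)
  tab <- data.frame(t = trace_times(r0), check.names = FALSE)
  labs <- make.unique(vapply(traces, `[[`, "", "label"))
  for (i in seq_along(traces)) tab[[labs[i]]] <- traces[[i]]$samples
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

seg_to_list <- function(seg) {
  list(cycle_start = seg$cycle_start,
       boundaries = as.list(seg$boundaries),
       cycle_end = seg$cycle_end,
       shift_indices = seg$shift_indices)
}

seg_from_list <- function(x) {
  phase_segmentation(unlist(x$boundaries[PHASE_NAMES]), x$cycle_end,
                     shift_indices = vapply(x$shift_indices, function(s)
                       if (is.null(s)) NA_integer_ else as.integer(s), 1L))
}

#' Write an analysis result to a JSON document
#'
#' Serializes every field of an [analysis_result()]; times are written with
#' full double precision (well beyond 6 significant digits) so results
#' round-trip through [read_result()] without loss.
#'
#' @param result an [analysis_result()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "analysis_result"))
  doc <- list(
    trace_label = result$trace_label,
    success = result$success,
    failure_reason = result$failure_reason,
    segmentations = lapply(result$segmentations, seg_to_list),
    peak_velocities = result$peak_velocities,
    intervals = if (!is.null(result$intervals))
      list(durations = as.list(result$intervals$durations)),
    acceleration_score = result$acceleration_score,
    filter_setting_used = result$filter_setting_used)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an analysis result written by [write_result()]
#'
#' @param path path to the JSON document.
#' @return an [analysis_result()].
#' @export
read_result <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_result: file not found: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path)
  iv <- if (!is.null(doc$intervals)) {
    d <- unlist(doc$intervals$durations[PHASE_NAMES])
    structure(list(durations = d), class = "interval_set")
  }
  analysis_result(
    trace_label = doc$trace_label,
    success = isTRUE(doc$success),
    failure_reason = doc$failure_reason,
    segmentations = lapply(doc$segmentations, seg_from_list),
    peak_velocities = doc$peak_velocities,
    intervals = iv,
    acceleration_score = if (is.null(doc$acceleration_score)) NA_integer_
      else doc$acceleration_score,
    filter_setting_used = if (is.null(doc$filter_setting_used)) NA_integer_
      else doc$filter_setting_used)
}
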