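#' Grade an acceleration trace with the 1-3 acceleration score
#'
#' A quantitative surrogate for the visual trace-quality grade: 3 means
#' clear and well-defined acceleration shifts, 2 less well-defined shifts,
#' often with a biphasic appearance, and 1 indistinct shifts with a
#' generally flat appearance. Shifts are abrupt changes of acceleration
#' level, so the features live in the jerk (rate of change of acceleration)
#' domain; all are ratios, making the score invariant to amplitude scaling:
#'
#' * `flatness` - contrast of the |acceleration| distribution, median |a|
#'   over its 95th percentile (1 for an identically-zero or constant-slope
#'   trace, small when distinct shifts stand out of a quiet baseline);
#' * `shift_prominence` - median over the six matched events of the largest
#'   |jerk| within one sample of the event, relative to the cycle's maximum
#'   |jerk| (needs a segmentation). Indistinct shifts, or noise flooding the
#'   jerk, drive it down;
#' * `biphasic_count` - number of matched events flanked (within
#'   `quality$biphasic_window` cycles, but clear of every matched boundary)
#'   by an additional prominent jerk peak: the signature of double-lobed
#'   (biphasic) shifts.
#'
#' Rules (thresholds in `config$quality`): flatness above 0.7 gives score 1;
#' otherwise two or more biphasic events or prominence below 0.25 gives
#' score 2; otherwise 3. Without a segmentation only flatness can be judged,
#' so non-flat unsegmented traces receive the middle grade.
#'
#' @param acc an [acceleration_trace()] spanning at least one cycle.
#' @param seg a [phase_segmentation()] for one cycle of `acc`, or `NULL`.
#' @param config configuration list (see [default_config()]).
#' @return list of class `quality_score`: `score` (1, 2 or 3) and `features`.
#' @export
acceleration_score <- function(acc, seg = NULL, config = default_config()) {
  stopifnot(inherits(acc, "acceleration_trace"))
  a <- acc$samples
  n <- length(a)
  if (n < 5L)
    stop("acceleration_score: empty or too-short trace", call. = FALSE)
  qc <- config$quality
  r <- acc$sampling_rate
  absa <- abs(a)
  p95 <- stats::quantile(absa, 0.95, names = FALSE)
  flatness <- if (p95 <= 1e-12) 1 else stats::median(absa) / p95

  prominence <- NA_real_
  biphasic <- NA_integer_
  if (!is.null(seg) && flatness <= qc$flatness_score1) {
    tt <- trace_times(acc)
    period <- seg$cycle_end - seg$cycle_start
    jk <- c(0, abs(a[3:n] - a[1:(n - 2L)]) * r / 2, 0)
    cyc <- which(tt >= seg$cycle_start & tt < seg$cycle_end)
    maxjk <- max(jk[cyc])
    if (maxjk > 0) {
      b <- seg$boundaries
      # jerk local maxima within the cycle
      dj <- diff(jk)
      pk <- which(dj[-(n - 1L)] * dj[-1L] < 0) + 1L
      pk <- pk[pk %in% cyc & jk[pk] >= qc$biphasic_rel * maxjk]
      guard <- qc$biphasic_guard_samples / r
      prom_e <- numeric(6L)
      biph_e <- logical(6L)
      for (e in 1:6) {
        near <- which(abs(tt - b[[e]]) <= 1.5 / r)
        prom_e[e] <- if (length(near) > 0L) max(jk[near]) / maxjk else 0
        w <- pk[abs(tt[pk] - b[[e]]) <= qc$biphasic_window * period]
        # peaks not explained by any matched boundary
        w <- w[vapply(w, function(j) all(abs(tt[j] - b) > guard), TRUE)]
        biph_e[e] <- length(w) >= 1L
      }
      prominence <- stats::median(prom_e)
      biphasic <- sum(biph_e)
    }
  }

  score <- if (flatness > qc$flatness_score1) 1L
  else if (is.na(prominence)) 2L
  else if (biphasic >= qc$biphasic_min || prominence < qc$prominence_score2) 2L
  else 3L

  structure(list(score = score,
                 features = list(shift_prominence = prominence,
                                 biphasic_count = biphasic,
                                 flatness = flatness)),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  f <- x$features
  cat(sprintf("<quality_score> %d (flatness %.2f, prominence %s, biphasic %s)\n",
              x$score, f$flatness,
              if (is.na(f$shift_prominence)) "NA" else sprintf("%.2f", f$shift_prominence),
              if (is.na(f$biphasic_count)) "NA" else f$biphasic_count))
  invisible(x)
}

#' Average acceleration scores per wall
#'
#' @param scores either a numeric vector of scores (returns one mean) or a
#'   data.frame with columns `wall` and `score` (returns one mean per wall).
#' @return numeric mean rounded to 2 decimals, or a data.frame
#'   `wall`/`mean_score`.
#' @examples
#' wall_average_score(c(3, 2))   # 2.5
#' @export
wall_average_score <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("wall", "score") %in% names(scores)), nrow(scores) > 0L)
    agg <- stats::aggregate(score ~ wall, data = scores,
                            FUN = function(s) round(mean(s), 2L))
    names(agg) <- c("wall", "mean_score")
    return(agg)
  }
  scores <- as.numeric(scores)
  if (length(scores) == 0L || any(!is.finite(scores)))
    stop("wall_average_score: need at least one finite score", call. = FALSE)
  round(mean(scores), 2L)
}
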