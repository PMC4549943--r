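#' Parameters of the synthetic fetal heart model
#'
#' Describes one simulated recording: fetal heart rate, the share of the
#' cycle taken by each of the six phases, peak velocities of the three main
#' waves (S during ejection, E during rapid filling, A during atrial
#' contraction), the amplitude of the brief pre-/post-ejection transients,
#' additive noise level, frame rate and number of cycles.
#'
#' Defaults are synthetic conventions, not measured values: a mid-range fetal
#' heart rate of 140 bpm, a 190 Hz frame rate (typical of fetal color-TDI
#' cine loops), peaks Sm +5.0, Em -6.0, Am -4.5 cm/s, and phase fractions
#' 0.15 / 0.05 / 0.35 / 0.05 / 0.25 / 0.15 in cycle order.
#'
#' @param heart_rate beats per minute, within the plausible fetal-monitoring
#'   range 80-220.
#' @param phase_fractions 6 positive fractions summing to 1, ordered as
#'   [phase_names()].
#' @param peak_s peak systolic velocity, cm/s (> 0).
#' @param peak_e peak early-diastolic velocity, cm/s (< 0).
#' @param peak_a peak atrial-contraction velocity, cm/s (< 0).
#' @param transient_amp amplitude of the pre-ejection (+) and post-ejection
#'   (-) spikes, cm/s.
#' @param noise_sd standard deviation of additive white Gaussian noise, cm/s.
#' @param frame_rate sampling frequency, Hz.
#' @param n_cycles number of complete cardiac cycles to simulate (>= 1).
#' @param ga_weeks gestational age in weeks (18-41), used for geometry.
#' @return list of class `heart_model_params`.
#' @export
heart_model_params <- function(heart_rate = 140,
                               phase_fractions = c(0.15, 0.05, 0.35,
                                                   0.05, 0.25, 0.15),
                               peak_s = 5.0, peak_e = -6.0, peak_a = -4.5,
                               transient_amp = 1.5, noise_sd = 0.5,
                               frame_rate = 190, n_cycles = 7L,
                               ga_weeks = 38) {
  if (!is.finite(heart_rate) || heart_rate < 80 || heart_rate > 220)
    stop("heart_model_params: heart_rate must be within 80-220 bpm", call. = FALSE)
  phase_fractions <- as.numeric(phase_fractions)
  if (length(phase_fractions) != 6L || any(phase_fractions <= 0))
    stop("heart_model_params: need 6 positive phase fractions", call. = FALSE)
  if (abs(sum(phase_fractions) - 1) > 1e-12)
    stop("heart_model_params: phase fractions must sum to 1", call. = FALSE)
  if (peak_s <= 0) stop("heart_model_params: peak_s must be > 0", call. = FALSE)
  if (peak_e >= 0) stop("heart_model_params: peak_e must be < 0", call. = FALSE)
  if (peak_a >= 0) stop("heart_model_params: peak_a must be < 0", call. = FALSE)
  if (noise_sd < 0) stop("heart_model_params: noise_sd must be >= 0", call. = FALSE)
  if (frame_rate <= 0) stop("heart_model_params: frame_rate must be > 0", call. = FALSE)
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L)
    stop("heart_model_params: n_cycles must be >= 1", call. = FALSE)
  names(phase_fractions) <- PHASE_NAMES
  structure(list(heart_rate = heart_rate, phase_fractions = phase_fractions,
                 peak_s = peak_s, peak_e = peak_e, peak_a = peak_a,
                 transient_amp = transient_amp, noise_sd = noise_sd,
                 frame_rate = frame_rate, n_cycles = n_cycles,
                 ga_weeks = ga_weeks),
            class = "heart_model_params")
}

#' Heart geometry for a gestational age
#'
#' Septal AV-plane-to-apex length defaults per gestational-age group to
#' 15.6 mm (GA I), 23.3 mm (GA II) and 32.5 mm (GA III); wall thickness to
#' 1.8, 2.9 and 3.6 mm, matching reported fetal dimensions at roughly 20, 30
#' and 40 weeks.
#'
#' @param ga_weeks gestational age in weeks (18-41).
#' @param ventricular_length_mm override AV-plane-to-apex length, mm.
#' @param wall_thickness_mm override wall thickness, mm.
#' @return list of class `heart_geometry`.
#' @examples
#' heart_geometry(21)$ventricular_length_mm   # 15.6
#' @export
heart_geometry <- function(ga_weeks, ventricular_length_mm = NULL,
                           wall_thickness_mm = NULL) {
  grp <- ga_group(ga_weeks)$name
  defaults <- switch(grp,
    GA_I   = c(len = 15.6, wall = 1.8),
    GA_II  = c(len = 23.3, wall = 2.9),
    GA_III = c(len = 32.5, wall = 3.6))
  len <- if (is.null(ventricular_length_mm)) defaults[["len"]] else ventricular_length_mm
  wall <- if (is.null(wall_thickness_mm)) defaults[["wall"]] else wall_thickness_mm
  if (len <= 0 || wall <= 0)
    stop("heart_geometry: dimensions must be positive", call. = FALSE)
  structure(list(ventricular_length_mm = len, wall_thickness_mm = wall,
                 ga_group = grp),
            class = "heart_geometry")
}

# Arched lobe family sin(pi u) * (1 + gamma * cos^2(pi u)) on u in [0, 1]:
# unit peak at mid-lobe, single-lobed for gamma in (-1, 0.5), nonzero edge
# slopes (half-sine-like arches). The acceleration of such a lobe approaches
# zero LINEARLY at both edges, so every junction between lobes carries a
# sharp acceleration feature exactly at the phase boundary: a zero crossing
# when the flanking lobes have opposite sign, a V-shaped near-zero touch
# when they share a sign. (Raised-cosine lobes, by contrast, have tangent
# edges whose acceleration features get absorbed into the neighboring lobe
# after smoothing, leaving two of the six boundaries unlocalizable at
# ~190 Hz.) Area is (2/pi) * (1 + gamma/3): gamma tunes displaced area
# without moving the peak.
lobe_area_factor <- function(gamma) 1 + gamma / 3

#' Build the AV-plane velocity waveform and its ground-truth events
#'
#' Constructs one cycle of the AV-plane longitudinal velocity as a sequence
#' of lobes, one per phase: an arched (half-sine-family) A-wave (atrial
#' contraction, negative), a brief biphasic pre-ejection transient
#' (positive-leading full sine), an arched S-wave (ejection, positive), a
#' biphasic post-ejection transient (negative-leading), an arched E-wave
#' (rapid filling, negative) and a flat diastasis (slow filling). Each main
#' wave is confined to its phase window and reaches exactly its configured
#' peak at mid-phase; the transients peak at `transient_amp`. Arched and
#' biphasic lobes meet with a velocity-slope break at every phase boundary,
#' i.e. a step in acceleration - a distinct "acceleration shift" at each of
#' the six onsets, which is the morphological premise of the analysis
#' method.
#'
#' Because the AV-plane returns to its end-cycle position each beat, the
#' velocity must integrate to zero over a cycle. Peaks are held exact; each
#' side's lobes instead get a shape factor `gamma` that fattens or slims the
#' arch, solved so positive and negative displacements cancel analytically.
#'
#' @param params a [heart_model_params()].
#' @return list with `fn` (vectorized velocity function of time in s, cm/s,
#'   periodic with the cycle), `period` (s), `onsets` (6 ground-truth phase
#'   onset times within one cycle, s) and `gammas` (per-lobe shape factors).
#' @export
build_waveform <- function(params) {
  stopifnot(inherits(params, "heart_model_params"))
  period <- 60 / params$heart_rate
  f <- params$phase_fractions
  onsets <- cumsum(c(0, f))[1:6]
  names(onsets) <- PHASE_NAMES
  amps <- c(params$peak_a, abs(params$transient_amp), params$peak_s,
            -abs(params$transient_amp), params$peak_e, 0)

  # The pre-/post-ejection transients are biphasic full-sine wiggles (the
  # typical isovolumic spike morphology) with zero net area, so displacement
  # balance concerns only the three main waves: fatten the lighter side
  # (gamma up to +0.45), then if needed slim the heavier side (gamma down to
  # -0.90). Peaks and the arched (nonzero-slope) edges are preserved.
  main <- c(1L, 3L, 5L)
  w_pos <- sum((amps * f)[main][amps[main] > 0])
  w_neg <- -sum((amps * f)[main][amps[main] < 0])
  gammas <- rep(0, 6L)
  if (w_pos > 0 && w_neg > 0 && w_pos != w_neg) {
    light <- seq_len(6L) %in% main &
      (if (w_pos < w_neg) amps > 0 else amps < 0)
    heavy <- seq_len(6L) %in% main &
      (if (w_pos < w_neg) amps < 0 else amps > 0)
    ratio <- max(w_pos, w_neg) / min(w_pos, w_neg)
    g_light <- min(3 * (ratio - 1), 0.45)
    gammas[light] <- g_light
    if (ratio / lobe_area_factor(g_light) > 1 + 1e-12) {
      g_heavy <- 3 * (lobe_area_factor(g_light) / ratio - 1)
      if (g_heavy < -0.90)
        stop("build_waveform: amplitude/fraction imbalance too large to balance displacement",
             call. = FALSE)
      gammas[heavy] <- g_heavy
    }
  } else if (xor(w_pos > 0, w_neg > 0)) {
    stop("build_waveform: cannot balance displacement with all lobes of one sign",
         call. = FALSE)
  }

  fn <- function(t) {
    u <- (t / period) %% 1
    v <- numeric(length(u))
    for (k in 1:5) {           # diastasis (k = 6) stays identically zero
      inl <- u >= onsets[k] & u < onsets[k] + f[k]
      if (any(inl)) {
        w <- (u[inl] - onsets[k]) / f[k]
        if (k %in% c(2L, 4L)) {
          v[inl] <- amps[k] * sin(2 * pi * w)
        } else {
          s <- sin(pi * w)
          v[inl] <- amps[k] * s * (1 + gammas[k] * (1 - s^2))
        }
      }
    }
    v
  }
  list(fn = fn, period = period, onsets = onsets * period,
       gammas = gammas)
}

#' Generate a synthetic spatiotemporal velocity field
#'
#' Produces velocities on a (depth below AV-plane) x (time) grid. The
#' noise-free field is the AV-plane waveform scaled by a linear apex-ward
#' decay, `1` at the AV-plane falling to `0` at the apex - the standard
#' base-to-apex gradient of longitudinal AV-plane motion. Additive white
#' Gaussian noise (sd `params$noise_sd`) is drawn reproducibly from `seed`.
#' Ground-truth phase onsets for every cycle are carried alongside.
#'
#' @param params a [heart_model_params()].
#' @param geometry a [heart_geometry()]; defaults to the geometry for
#'   `params$ga_weeks`.
#' @param seed integer RNG seed.
#' @param depth_step_mm spatial grid resolution in mm (default 0.25).
#' @param start_phase cycle phase (in `[0, 1)`) at which the recording
#'   begins, or `NULL` (default) to draw it uniformly from `seed` - cine
#'   loops start at an arbitrary point of the cycle. The recording spans
#'   `n_cycles + 1` cycle lengths so that `n_cycles` complete cycles fall
#'   inside it regardless of the start phase.
#' @return list of class `velocity_field` with `positions` (mm), `times` (s),
#'   `values` (positions x times matrix, cm/s), `clean` (noise-free matrix),
#'   `ground_truth` (list of [phase_segmentation()]), `params`, `geometry`,
#'   `seed`.
#' @export
generate_field <- function(params, geometry = heart_geometry(params$ga_weeks),
                           seed = 1L, depth_step_mm = 0.25,
                           start_phase = NULL) {
  stopifnot(inherits(params, "heart_model_params"),
            inherits(geometry, "heart_geometry"))
  wf <- build_waveform(params)
  L <- geometry$ventricular_length_mm
  positions <- seq(0, L, by = depth_step_mm)
  if (positions[length(positions)] < L) positions <- c(positions, L)
  n_t <- max(2L, round((params$n_cycles + 1L) * wf$period * params$frame_rate))
  times <- (seq_len(n_t) - 1L) / params$frame_rate
  decay <- 1 - positions / L
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  if (is.null(start_phase)) start_phase <- stats::runif(1)
  if (start_phase < 0 || start_phase >= 1)
    stop("generate_field: start_phase must be in [0, 1)", call. = FALSE)
  base <- wf$fn(times + start_phase * wf$period)
  clean <- outer(decay, base)
  values <- clean
  if (params$noise_sd > 0)
    values <- clean + matrix(stats::rnorm(length(clean), sd = params$noise_sd),
                             nrow = nrow(clean))
  # Ground truth for every complete cycle inside the recording ("complete"
  # up to half a sample of slack, matching the analyzer's convention).
  t_end <- times[n_t]
  m <- if (start_phase == 0) 0L else 1L
  gt <- list()
  repeat {
    t0 <- (m - start_phase) * wf$period
    if (t0 + wf$period > t_end + 0.5 / params$frame_rate) break
    gt[[length(gt) + 1L]] <- phase_segmentation(t0 + wf$onsets,
                                                cycle_end = t0 + wf$period)
    m <- m + 1L
  }
  structure(list(positions = positions, times = times, values = values,
                 clean = clean, ground_truth = gt, params = params,
                 geometry = geometry, seed = as.integer(seed),
                 start_phase = start_phase, waveform = wf),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d depths x %d frames, %s (L = %g mm), %d cycles @ %g bpm\n",
              length(x$positions), length(x$times), x$geometry$ga_group,
              x$geometry$ventricular_length_mm, x$params$n_cycles,
              x$params$heart_rate))
  invisible(x)
}

#' Sample an ROI from a velocity field
#'
#' The trace is the unweighted spatial mean of the field over the depths the
#' ROI covers, `[center_offset - height/2, center_offset + height/2]` below
#' the AV-plane. ROI width is metadata only: the 1-D field has no across-wall
#' variation. By default the ROI top edge sits at the AV-plane.
#'
#' @param field a [generate_field()] result.
#' @param roi an [roi_spec()]; must lie within the ventricular length.
#' @param label label for the returned trace.
#' @param clean if `TRUE`, sample the noise-free field.
#' @return a [velocity_trace()].
#' @export
sample_roi <- function(field, roi, label = "synthetic", clean = FALSE) {
  stopifnot(inherits(field, "velocity_field"), inherits(roi, "roi_spec"))
  top <- roi$center_offset_mm - roi$height_mm / 2
  bottom <- roi$center_offset_mm + roi$height_mm / 2
  L <- field$geometry$ventricular_length_mm
  if (top < -1e-9 || bottom > L + 1e-9)
    stop("sample_roi: ROI extends above the AV-plane or beyond the apex",
         call. = FALSE)
  rows <- which(field$positions >= top - 1e-9 & field$positions <= bottom + 1e-9)
  if (length(rows) == 0L)
    rows <- which.min(abs(field$positions - roi$center_offset_mm))
  mat <- if (clean) field$clean else field$values
  v <- if (length(rows) == 1L) mat[rows, ] else colMeans(mat[rows, , drop = FALSE])
  velocity_trace(v, sampling_rate = field$params$frame_rate,
                 time_start = field$times[1L], label = label, roi = roi)
}

# Counter-based fan-out of one master seed into independent per-trace seeds,
# kept below 2^31 so they are valid R integer seeds.
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 65011 * 32771 + index * 2654435.0) %% 2147483629 + 1)
}

#' Generate a reproducible batch of synthetic traces with ground truth
#'
#' Each trace is an independently seeded recording of 5-10 complete cardiac
#' cycles (the usual cine-loop length), with its own heart rate drawn from
#' the typical fetal range 110-160 bpm and a noise level cycled through
#' `noise_grid`. Per-trace seeds are derived from the master seed by a
#' counter scheme, so any subset of the batch reproduces independently.
#'
#' @param n_traces number of traces (>= 1).
#' @param noise_grid numeric vector of noise standard deviations, cm/s,
#'   recycled across traces.
#' @param ga_weeks gestational age in weeks; fixes the geometry.
#' @param seed master integer seed.
#' @param roi [roi_spec()] used to sample every trace; default the 2 x 2 mm
#'   reference ROI.
#' @param params_fn optional function(heart_rate, noise_sd, n_cycles) ->
#'   [heart_model_params()], to customize amplitudes or fractions.
#' @return list with one element per trace: `trace`, `ground_truth`,
#'   `params`, `seed`.
#' @export
generate_dataset <- function(n_traces, noise_grid = 0.5, ga_weeks = 38,
                             seed = 1L, roi = roi_spec(2, 2),
                             params_fn = NULL) {
  n_traces <- as.integer(n_traces)
  if (is.na(n_traces) || n_traces < 1L)
    stop("generate_dataset: n_traces must be >= 1", call. = FALSE)
  if (length(noise_grid) == 0L)
    stop("generate_dataset: noise grid must be non-empty", call. = FALSE)
  lapply(seq_len(n_traces), function(i) {
    si <- derive_seed(seed, i)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(si)
    hr <- stats::runif(1, 110, 160)
    nc <- sample(5:10, 1L)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    ns <- noise_grid[(i - 1L) %% length(noise_grid) + 1L]
    params <- if (is.null(params_fn))
      heart_model_params(heart_rate = hr, noise_sd = ns, n_cycles = nc,
                         ga_weeks = ga_weeks)
    else params_fn(heart_rate = hr, noise_sd = ns, n_cycles = nc)
    field <- generate_field(params, seed = si)
    list(trace = sample_roi(field, roi, label = sprintf("trace_%03d", i)),
         ground_truth = field$ground_truth,
         params = params, seed = si)
  })
}
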