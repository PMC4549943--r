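# Shared fixtures, generated in code (no data files).

# Noise-free reference field + 2x2 mm trace for a GA III fetus.
clean_field <- function(seed = 5, noise_sd = 0, n_cycles = 7L, ...) {
  generate_field(heart_model_params(noise_sd = noise_sd, n_cycles = n_cycles,
                                    ...),
                 seed = seed)
}

clean_trace <- function(seed = 5, ...) {
  sample_roi(clean_field(seed = seed, ...), roi_spec(2, 2))
}

# Boundary errors (in samples) of each successful segmentation against the
# nearest ground-truth cycle.
boundary_errors <- function(result, field) {
  rate <- field$params$frame_rate
  t(vapply(result$segmentations, function(s) {
    d <- vapply(field$ground_truth, function(g) abs(g$cycle_start - s$cycle_start), 0)
    g <- field$ground_truth[[which.min(d)]]
    (s$boundaries - g$boundaries) * rate
  }, numeric(6L)))
}

# Trace with double-lobed (biphasic) wiggles injected after the atrial and
# slow-filling onsets of every cycle - the canonical score-2 fixture.
biphasic_trace <- function(seed = 5, amp = 0.8, width_samples = 6) {
  field <- clean_field(seed = seed)
  tr <- sample_roi(field, roi_spec(2, 2))
  r <- tr$sampling_rate
  tt <- trace_times(tr)
  W <- width_samples / r
  for (g in field$ground_truth) {
    for (b in g$boundaries[c(1L, 6L)]) {
      t0 <- b + 3.5 / r
      inw <- tt >= t0 - W / 2 & tt < t0 + W / 2
      tr$samples[inw] <- tr$samples[inw] +
        amp * sin(2 * pi * (tt[inw] - t0 + W / 2) / W)
    }
  }
  tr
}

# Brute-force oracle for the constrained template assignment: exhaustive
# enumeration over ordered 5-subsets of candidates for events 2..6.
brute_force_assignment <- function(frac, kind, template) {
  m <- length(frac)
  best <- Inf
  feas <- lapply(2:6, function(e)
    which(abs(frac - template$prior_fractions[e]) <= template$tolerance[e] &
            kind %in% template$required_kinds[[e]] & frac > 0 & frac < 1))
  rec <- function(e, prev_frac, cost) {
    if (cost >= best) return()
    if (e > 5L) { best <<- cost; return() }
    for (j in feas[[e]]) {
      if (frac[j] > prev_frac + 1e-12)
        rec(e + 1L, frac[j],
            cost + (frac[j] - template$prior_fractions[e + 1L])^2)
    }
  }
  rec(1L, 0, 0)
  if (is.finite(best)) best else NULL
}
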