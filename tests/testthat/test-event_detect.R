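test_that("a cosine period yields exactly 2 crossings and 2 extrema", {
  r <- 200
  t <- seq(-0.3, 0.7, by = 1 / r)
  acc <- acceleration_trace(cos(2 * pi * t), r, time_start = -0.3)
  cand <- detect_shifts(acc, c(-0.3, 0.7))
  expect_equal(sum(cand$kind == "zero_crossing"), 2L)
  expect_equal(sum(cand$kind == "local_extremum"), 2L)
  expect_equal(nrow(cand), 4L)
  expect_equal(sort(cand$time), c(-0.25, 0, 0.25, 0.5), tolerance = 1 / r)
  expect_true(all(diff(cand$time) > 0))
})

test_that("identically-zero acceleration yields no candidates", {
  acc <- acceleration_trace(rep(0, 100), 190)
  expect_equal(nrow(detect_shifts(acc, c(0, 0.5))), 0L)
  expect_error(detect_shifts(acc, c(0.2, 0.201)), "window")
})

test_that("noise-free cycles contain all six onsets among the candidates", {
  f <- clean_field(seed = 6)
  tr <- sample_roi(f, roi_spec(2, 2))
  filt <- filter_bank(moving_average(tr, 3), 1)
  acc <- acceleration(filt)
  g <- f$ground_truth[[3]]
  # pad the window edge so the atrial-onset shift is interior to it
  cand <- detect_shifts(acc, c(g$cycle_start - 5 / 190, g$cycle_end))
  expect_gte(nrow(cand), 10L)
  for (b in g$boundaries)
    expect_lt(min(abs(cand$time - b)), 1 / 190)
})

test_that("template assignment is a fixed point on exact-prior candidates", {
  # acceleration with sharp alternating steps exactly at the prior onsets
  r <- 190
  period <- 60 / 140
  tmpl <- default_event_template()
  t <- seq(0, period, by = 1 / r)
  a <- numeric(length(t))
  lev <- c(-1, 1, -1, 1, -1, 0.0)
  for (e in 2:6) a[t >= tmpl$prior_fractions[e] * period] <- lev[e]
  acc <- acceleration_trace(a + 1e-6 * sin(200 * t), r)
  vel <- velocity_trace(cumsum(a) / r, r)
  seg <- segment_cycle(vel, acc, c(0, period), tmpl)
  expect_s3_class(seg, "phase_segmentation")
  for (e in 2:6)
    expect_lt(abs(seg$boundaries[e] - tmpl$prior_fractions[e] * period),
              1.5 / r)
})

test_that("too few or unmatchable candidates raise classed failures", {
  r <- 190
  period <- 0.5
  t <- seq(0, period, by = 1 / r)
  # a pure sinusoid gives only ~4 candidates
  acc <- acceleration_trace(sin(2 * pi * t / period), r)
  vel <- velocity_trace(cos(2 * pi * t / period), r)
  expect_error(segment_cycle(vel, acc, c(0, period), default_event_template()),
               class = "fetaltdi_insufficient_shifts")

  # many candidates, but all in the first 10 % of the cycle
  a2 <- ifelse(t < 0.1 * period, sin(200 * pi * t), 0)
  acc2 <- acceleration_trace(a2, r)
  expect_error(segment_cycle(vel, acc2, c(0, period), default_event_template()),
               class = "fetaltdi_template_mismatch")
})

test_that("assignment optimum equals exhaustive enumeration (oracle)", {
  tmpl <- default_event_template()
  set.seed(99)
  n_checked <- 0L
  for (rep in 1:60) {
    m <- sample(6:12, 1)
    frac <- sort(runif(m, 0.02, 0.98))
    kind <- sample(c("zero_crossing", "local_extremum", "step"), m,
                   replace = TRUE)
    dp <- fetaltdi:::assign_events(frac, kind, tmpl)
    oracle <- brute_force_assignment(frac, kind, tmpl)
    if (is.null(oracle)) {
      expect_null(dp)
    } else {
      expect_false(is.null(dp))
      cost <- sum((frac[dp] - tmpl$prior_fractions[2:6])^2)
      expect_equal(cost, oracle, tolerance = 1e-12)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10L)   # enough feasible instances actually compared
})

test_that("analyze_trace succeeds on clean traces and encodes failures", {
  f <- clean_field(seed = 3, n_cycles = 7L)
  res <- analyze_trace(sample_roi(f, roi_spec(2, 2)))
  expect_true(res$success)
  expect_equal(res$filter_setting_used, 1L)
  expect_gte(length(res$segmentations), 6L)
  for (s in res$segmentations) {
    expect_true(all(diff(s$boundaries) > 0))
    expect_equal(sum(interval_durations(s)$durations),
                 (s$cycle_end - s$cycle_start) * 1000)
  }

  set.seed(21)
  noise <- velocity_trace(rnorm(600), 190)
  rn <- analyze_trace(noise)
  expect_false(rn$success)
  expect_equal(rn$failure_reason, "no_periodicity")

  flat <- velocity_trace(rep(0.5, 400), 190)
  expect_equal(analyze_trace(flat)$failure_reason, "degenerate_input")
})

test_that("success fraction is non-increasing in the noise level", {
  grid <- c(0, 0.5, 1, 2, 4)
  frac <- vapply(seq_along(grid), function(i) {
    batch <- generate_dataset(8, noise_grid = grid[i], ga_weeks = 38,
                              seed = 40 + i)
    mean(vapply(batch, function(b) analyze_trace(b$trace)$success, TRUE))
  }, 0)
  expect_true(all(diff(frac) <= 0))
})

test_that("segmentation timing is invariant to ROI size", {
  f <- clean_field(seed = 12)
  ref <- analyze_trace(sample_roi(f, roi_spec(2, 4)))
  expect_true(ref$success)
  for (h in c(4, 6, 8)) {
    r <- analyze_trace(sample_roi(f, roi_spec(h, 4)))
    expect_true(r$success)
    d_ref <- ref$intervals$durations
    d <- r$intervals$durations
    expect_true(all(abs(d - d_ref) / d_ref <= 0.03))
  }
})
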