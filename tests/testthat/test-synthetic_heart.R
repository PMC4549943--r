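test_that("waveform peaks, period and ground-truth onsets are exact", {
  p <- heart_model_params(heart_rate = 140, noise_sd = 0)
  wf <- build_waveform(p)
  expect_equal(wf$period, 60 / 140)
  # peak of the ejection lobe equals peak_s exactly at mid-phase
  mid_ej <- wf$onsets[["ejection"]] + 0.5 * 0.35 * wf$period
  expect_equal(wf$fn(mid_ej), 5.0, tolerance = 1e-12)
  grid <- seq(wf$onsets[["ejection"]], wf$onsets[["post_ejection"]],
              length.out = 10001)
  expect_lte(max(wf$fn(grid)), 5.0 + 1e-9)
  expect_equal(unname(wf$onsets),
               unname(cumsum(c(0, p$phase_fractions))[1:6]) * wf$period)
  expect_error(heart_model_params(phase_fractions = rep(0.2, 6)), "sum to 1")
})

test_that("waveform displaces zero net volume per cycle (quadrature oracle)", {
  for (hr in c(110, 140, 160)) {
    wf <- build_waveform(heart_model_params(heart_rate = hr))
    tg <- seq(0, wf$period, length.out = 1e5 + 1)
    v <- wf$fn(tg)
    disp <- sum((v[-1] + v[-length(v)]) / 2) * (tg[2] - tg[1])
    expect_lt(abs(disp), 1e-9)
  }
})

test_that("field generation is seed-deterministic", {
  p <- heart_model_params(noise_sd = 0.8)
  f1 <- generate_field(p, seed = 123)
  f2 <- generate_field(p, seed = 123)
  expect_identical(f1$values, f2$values)
  expect_identical(f1$start_phase, f2$start_phase)
  f3 <- generate_field(p, seed = 124)
  expect_false(identical(f1$values, f3$values))
})

test_that("noise-free field decays linearly to zero at the apex", {
  p <- heart_model_params(noise_sd = 0)
  f <- generate_field(p, seed = 1, start_phase = 0)
  L <- f$geometry$ventricular_length_mm
  apex <- which(f$positions == L)
  expect_true(all(f$values[apex, ] == 0))
  half <- which(abs(f$positions - L / 2) < 1e-9)
  expect_equal(f$values[half, ], 0.5 * f$values[1, ], tolerance = 1e-12)
  # |v| non-increasing with depth at every time point
  mags <- abs(f$values)
  expect_true(all(diff(mags) <= 1e-12))
})

test_that("field noise has the configured moments (Monte-Carlo check)", {
  p <- heart_model_params(noise_sd = 0.7, n_cycles = 5L)
  f <- generate_field(p, seed = 77)
  eps <- f$values - f$clean
  n <- length(eps)
  expect_gt(n, 1e4)
  se_mean <- 0.7 / sqrt(n)
  expect_lt(abs(mean(eps)), 3 * se_mean)
  se_sd <- 0.7 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(eps) - 0.7), 3 * se_sd)
})

test_that("ROI sampling averages depths and honors placement limits", {
  p <- heart_model_params(noise_sd = 0)
  f <- generate_field(p, seed = 2, start_phase = 0)
  # vanishing ROI height reduces to the AV-plane row
  tiny <- sample_roi(f, roi_spec(1e-6, 2))
  expect_equal(tiny$samples, f$values[1, ], tolerance = 1e-6)
  # peak |S| non-increasing across growing ROI heights
  peaks <- vapply(c(2, 4, 6, 8), function(h)
    max(sample_roi(f, roi_spec(h, 4))$samples), 0)
  expect_true(all(diff(peaks) <= 1e-12))
  expect_error(sample_roi(f, roi_spec(70, 4)), "beyond the apex")
  expect_error(roi_spec(4, 4, center_offset_mm = 0), "center_offset")
})

test_that("dataset batches are reproducible with 5-10 cycles per trace", {
  b1 <- generate_dataset(10, noise_grid = c(0, 0.5), ga_weeks = 35, seed = 7)
  b2 <- generate_dataset(10, noise_grid = c(0, 0.5), ga_weeks = 35, seed = 7)
  expect_identical(lapply(b1, `[[`, "trace"), lapply(b2, `[[`, "trace"))
  expect_equal(b1[[1]]$trace$sampling_rate, 190)
  for (b in b1) {
    expect_gte(length(b$ground_truth), 5L)
    expect_lte(length(b$ground_truth), 10L)
    expect_true(b$params$heart_rate >= 110 && b$params$heart_rate <= 160)
  }
  # GA III geometry
  f <- generate_field(heart_model_params(ga_weeks = 35), seed = 1)
  expect_equal(f$geometry$ventricular_length_mm, 32.5)
  expect_equal(heart_geometry(20)$ventricular_length_mm, 15.6)
  expect_equal(heart_geometry(29)$ventricular_length_mm, 23.3)
  expect_error(generate_dataset(3, noise_grid = numeric(0)), "non-empty")
})

test_that("ground-truth segmentations satisfy the phase invariants", {
  f <- clean_field(seed = 4)
  for (g in f$ground_truth) {
    expect_true(all(diff(g$boundaries) > 0))
    durs <- interval_durations(g)$durations
    expect_equal(sum(durs), (g$cycle_end - g$cycle_start) * 1000)
  }
})
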