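test_that("peak velocities recover the configured amplitudes and signs", {
  f <- clean_field(seed = 4)
  # near-AV-plane ROI: minimal spatial attenuation
  tr <- sample_roi(f, roi_spec(0.5, 2))
  res <- analyze_trace(tr)
  expect_true(res$success)
  pv <- res$peak_velocities
  expect_lt(abs(pv$sm - 5.0) / 5.0, 0.05)
  expect_lt(abs(pv$em - (-6.0)) / 6.0, 0.05)
  expect_lt(abs(pv$am - (-4.5)) / 4.5, 0.05)
  expect_gt(pv$sm, 0)
  expect_lt(pv$em, 0)
  expect_lt(pv$am, 0)
})

test_that("polarity inversion with the invert flag is a no-op", {
  tr <- clean_trace(seed = 9, noise_sd = 0.3)
  inv <- tr
  inv$samples <- -inv$samples
  r1 <- analyze_trace(tr)
  r2 <- analyze_trace(inv, invert = TRUE)
  expect_equal(r1$peak_velocities, r2$peak_velocities)
  expect_equal(r1$segmentations, r2$segmentations)
})

test_that("interval durations partition the cycle exactly", {
  seg <- phase_segmentation(c(0, 0.06, 0.09, 0.24, 0.26, 0.37), 0.43)
  iv <- interval_durations(seg)
  expect_equal(sum(iv$durations), 430)
  expect_named(iv$durations, phase_names())
  expect_true(all(iv$durations > 0))

  # noise-free 140 bpm: ejection = 0.35 * 428.57 ms = 150 ms within 1 frame
  f <- clean_field(seed = 3, heart_rate = 140)
  res <- analyze_trace(sample_roi(f, roi_spec(2, 2)))
  expect_true(res$success)
  expect_lt(abs(res$intervals$durations[["ejection"]] - 150.0), 1000 / 190)
  expect_true(all(res$intervals$durations >= 1000 / 190))
})

test_that("percent differences follow the magnitude convention", {
  expect_equal(percent_difference(5.0, 5.0), 0)
  expect_equal(percent_difference(4.5, 5.0), -10)
  expect_equal(percent_difference(-4.2, -6.0, use_magnitude = TRUE), -30)
  expect_error(percent_difference(1, 0), "zero reference")
  set.seed(13)
  v <- runif(100, 1, 10); ref <- runif(100, 1, 10)
  got <- percent_difference(v, ref)
  oracle <- vapply(1:100, function(i) 100 * (v[i] - ref[i]) / ref[i], 0)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("difference summaries use linear-interpolation quantiles", {
  s1 <- summarize_differences(-10)
  expect_equal(s1$median_pct, -10)
  expect_equal(s1$iqr_pct, 0)
  expect_equal(summarize_differences(c(1, 2, 3, 4))$median_pct, 2.5)
  expect_error(summarize_differences(numeric(0)), "empty")

  set.seed(17)
  x <- rnorm(500) * 20
  s <- summarize_differences(x)
  # sort-based type-7 quantile oracle
  q7 <- function(p) {
    xs <- sort(x); h <- (length(xs) - 1) * p
    lo <- floor(h)
    xs[lo + 1] + (h - lo) * (xs[lo + 2 - (lo == length(xs) - 1)] - xs[lo + 1])
  }
  expect_equal(s$median_pct, q7(0.5), tolerance = 1e-12)
  expect_equal(s$iqr_pct, q7(0.75) - q7(0.25), tolerance = 1e-12)
})

test_that("feasibility reproduces printed percentages from counts", {
  fs <- feasibility(data.frame(
    wall = c("right_wall", "left_wall", "septum"),
    n_success = c(81, 71, 51), n_total = c(87, 87, 87)))
  expect_equal(fs$per_wall$pct, c(93, 82, 59))
  expect_equal(fs$overall$n_success, 203)
  expect_equal(fs$overall$n_total, 261)
  expect_equal(fs$overall$pct, 78)
  expect_equal(feasibility(data.frame(wall = "septum", n_success = 0,
                                      n_total = 10))$overall$pct, 0)
  expect_error(feasibility(data.frame(wall = "x", n_success = 5, n_total = 4)),
               "exceeds")
})

test_that("feasibility aggregates analysis results by wall label", {
  ok <- analysis_result("septum", TRUE,
                        segmentations = list(
                          phase_segmentation(c(0, .1, .2, .3, .4, .5), 0.6)))
  bad <- analysis_result("septum", FALSE, failure_reason = "no_periodicity")
  ok2 <- analysis_result("left_wall", TRUE,
                         segmentations = list(
                           phase_segmentation(c(0, .1, .2, .3, .4, .5), 0.6)))
  fs <- feasibility(list(ok, bad, ok2))
  sept <- fs$per_wall[fs$per_wall$wall == "septum", ]
  expect_equal(sept$n_success, 1)
  expect_equal(sept$n_total, 2)
  expect_equal(fs$overall$pct, 67)
})

test_that("ROI fractions reproduce every printed ladder percentage", {
  expect_equal(roi_fraction(2, 15.6), 13)
  expect_equal(roi_fraction(8, 32.5), 25)
  expect_equal(roi_fraction(10, 10), 100)
  ga1 <- vapply(c(2, 3, 4), roi_fraction, 0, septal_length_mm = 15.6)
  expect_equal(ga1, c(13, 19, 26))
  ga2 <- vapply(c(2, 3, 4, 6), roi_fraction, 0, septal_length_mm = 23.3)
  expect_equal(ga2, c(9, 13, 17, 26))
  ga3 <- vapply(c(2, 3, 4, 6, 8), roi_fraction, 0, septal_length_mm = 32.5)
  expect_equal(ga3, c(6, 9, 12, 18, 25))
  expect_error(roi_fraction(0, 10), "positive")
  expect_error(roi_fraction(2, -1), "positive")
})

test_that("ROI recommendations follow the gestational-age groups", {
  r1 <- recommend_roi(20)
  expect_equal(c(r1$height_mm, r1$width_mm), c(2, 2))
  r2 <- recommend_roi(29)
  expect_equal(c(r2$height_mm, r2$width_mm), c(4, 3))
  r3 <- recommend_roi(38)
  expect_equal(c(r3$height_mm, r3$width_mm), c(6, 4))
  expect_error(recommend_roi(10), "18-41")
})

test_that("the ROI study shows velocity attenuation but stable intervals", {
  tab <- roi_study(38, seed = 1, noise_sd = 0)
  vel <- tab[tab$metric %in% c("sm", "em", "am"), ]
  for (m in c("sm", "em", "am")) {
    med <- vel$median_pct[vel$metric == m][order(vel$roi_height_mm[vel$metric == m])]
    expect_true(all(med <= 0))
    expect_true(all(diff(med) < 0))   # strictly more attenuation, larger ROI
  }
  ivs <- tab[!tab$metric %in% c("sm", "em", "am"), ]
  expect_true(all(abs(ivs$median_pct) <= 3))
})
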