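test_that("trace tables read correctly and infer the sampling rate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,septum", "0,0.0", "0.005,1.0", "0.010,2.0"), f)
  traces <- read_trace_table(f)
  expect_length(traces, 1L)
  expect_equal(traces[[1]]$sampling_rate, 200)
  expect_equal(traces[[1]]$samples, c(0, 1, 2))
  expect_equal(traces[[1]]$label, "septum")
})

test_that("malformed trace tables are rejected with distinct errors", {
  one_row <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,v", "0,1.0"), one_row)
  expect_error(read_trace_table(one_row), "fewer than 2")

  nonmono <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,v", "0,1", "0.01,2", "0.005,3"), nonmono)
  expect_error(read_trace_table(nonmono), "not strictly increasing")

  nonunif <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,v", "0,1", "0.005,2", "0.02,3"), nonunif)
  expect_error(read_trace_table(nonunif), "non-uniform")

  expect_error(read_trace_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("trace write/read round-trips 500 random samples", {
  set.seed(42)
  tr <- velocity_trace(rnorm(500), sampling_rate = 190, label = "left_wall")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_table(tr, f)
  back <- read_trace_table(f)[[1]]
  expect_equal(back$samples, tr$samples, tolerance = 1e-9)
  expect_equal(back$sampling_rate, tr$sampling_rate, tolerance = 1e-9)
  expect_equal(back$label, tr$label)
})

test_that("dialects with alternative delimiter and decimal mark work", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t\tv", "0\t0,5", "0,005\t1,5", "0,01\t2,5"), f)
  tr <- read_trace_table(f, delimiter = "\t", decimal = ",")[[1]]
  expect_equal(tr$samples, c(0.5, 1.5, 2.5))
  expect_equal(tr$sampling_rate, 200)
})

test_that("type constructors enforce their invariants", {
  expect_error(velocity_trace(1, 190), "at least 2")
  expect_error(velocity_trace(c(1, NA), 190), "finite")
  expect_error(velocity_trace(c(1, 2), -1), "positive")
  expect_error(roi_spec(0, 2), "height_mm")
  expect_error(roi_spec(2, 2, center_offset_mm = 0), "center_offset_mm")
  expect_silent(roi_spec(2, 2))          # default offset = height / 2

  expect_error(phase_segmentation(c(0, .1, .2, .15, .3, .4), 0.5),
               "strictly increasing")
  expect_error(phase_segmentation(seq(0, 0.5, by = 0.1), 0.5), "cycle_end")

  expect_equal(ga_group(18)$name, "GA_I")
  expect_equal(ga_group(24)$name, "GA_I")
  expect_equal(ga_group(25)$name, "GA_II")
  expect_equal(ga_group(33)$name, "GA_III")
  expect_error(ga_group(17), "18-41")
  expect_error(ga_group(42), "18-41")

  expect_error(analysis_result("x", success = FALSE), "failure_reason")
  seg <- phase_segmentation(c(0, .1, .2, .3, .4, .5), 0.6)
  expect_error(analysis_result("x", success = FALSE,
                               failure_reason = "no_periodicity",
                               segmentations = list(seg)),
               "no segmentations")
})

test_that("results round-trip through JSON with full precision", {
  tr <- clean_trace(seed = 8)
  res <- analyze_trace(tr)
  expect_true(res$success)
  f <- withr::local_tempfile(fileext = ".json")
  write_result(res, f)
  back <- read_result(f)
  expect_equal(back$trace_label, res$trace_label)
  expect_equal(length(back$segmentations), length(res$segmentations))
  for (i in seq_along(res$segmentations)) {
    expect_equal(back$segmentations[[i]]$boundaries,
                 res$segmentations[[i]]$boundaries, tolerance = 1e-9)
    expect_equal(back$segmentations[[i]]$cycle_end,
                 res$segmentations[[i]]$cycle_end, tolerance = 1e-9)
  }
  expect_equal(back$peak_velocities$sm, res$peak_velocities$sm,
               tolerance = 1e-9)
  expect_equal(unclass(back$intervals)$durations,
               unclass(res$intervals)$durations, tolerance = 1e-9)
  expect_equal(back$acceleration_score, res$acceleration_score)
  expect_equal(back$filter_setting_used, res$filter_setting_used)
})

test_that("failed results serialize with empty segmentations", {
  res <- analysis_result("septum", success = FALSE,
                         failure_reason = "no_periodicity")
  f <- withr::local_tempfile(fileext = ".json")
  write_result(res, f)
  back <- read_result(f)
  expect_false(back$success)
  expect_equal(back$failure_reason, "no_periodicity")
  expect_length(back$segmentations, 0L)
})
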