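test_that("modulation patterns reproduce the protocol timing and point counts", {
  p10 <- daq_pattern("DAQ10")
  p48 <- daq_pattern("DAQ48")
  expect_equal(p10$nominal_points, 6000)
  expect_equal(p48$nominal_points, 28800)
  # total trace duration = nominal points at 10 Hz, with active stages at
  # their scheduled durations
  expect_equal(p10$preheat[["duration"]] + sum(p10$stages$duration), 600)
  expect_equal(p48$preheat[["duration"]] + sum(p48$stages$duration), 2880)
  expect_equal(sum(p10$stages$duration[p10$stages$active]), 5 * 30)
  expect_equal(sum(p48$stages$duration[p48$stages$active]), 5 * 300)
})

test_that("splitting extracts five ordered level segments of the scheduled length", {
  for (id in c("DAQ10", "DAQ48")) {
    pat <- daq_pattern(id)
    tr <- matrix(rnorm(5 * pat$nominal_points), nrow = 5)
    segs <- split_modulation_levels(tr, pat)
    expect_length(segs, 5)
    expect_equal(names(segs), c("7", "5.5", "5", "6", "6.5"))
    expected_m <- if (id == "DAQ10") 300 else 3000
    expect_true(all(vapply(segs, ncol, integer(1)) == expected_m))
  }
})

test_that("active segments partition disjoint index ranges covering the active time", {
  pat <- daq_pattern("DAQ48")
  spans <- odourfusion:::active_spans(pat)
  idx <- unlist(lapply(spans, function(s) s$from:s$to))
  expect_equal(length(idx), length(unique(idx)))          # disjoint
  expect_equal(sort(idx), idx)                            # ordered
  expect_equal(length(idx), sum(pat$stages$duration[pat$stages$active]) *
                 pat$sampling_rate)
})

test_that("a constant trace yields constant segments and a short trace errors", {
  pat <- daq_pattern("DAQ10")
  segs <- split_modulation_levels(matrix(3.5, 5, 6000), pat)
  for (s in segs) expect_true(all(s == 3.5))
  expect_error(split_modulation_levels(matrix(0.1, 5, 5000), pat), "short by 1000")
})

test_that("baseline subtraction uses the first-five-sample mean", {
  expect_equal(as.numeric(subtract_baseline(matrix(c(1, 1, 1, 1, 1, 3), 1))),
               c(0, 0, 0, 0, 0, 2))
  expect_equal(as.numeric(subtract_baseline(matrix(c(0, 5, 0, 5, 0, 7), 1))),
               c(-2, 3, -2, 3, -2, 5))
  expect_true(all(subtract_baseline(matrix(4.2, 3, 10)) == 0))
  # per-sensor anchoring: first-five mean of the output is zero
  m <- matrix(rnorm(5 * 40), 5)
  out <- subtract_baseline(m)
  expect_equal(rowMeans(out[, 1:5]), rep(0, 5), tolerance = 1e-12)
  expect_error(subtract_baseline(matrix(1, 5, 4)), "at least 5")
})

test_that("min-max segment scaling maps to [0,1] with zero-range rows to zero", {
  expect_equal(as.numeric(scale_segment(matrix(c(2, 4, 6), 1))), c(0, 0.5, 1))
  expect_true(all(scale_segment(matrix(7, 2, 8)) == 0))
  m <- matrix(rnorm(5 * 30), 5)
  out <- scale_segment(m)
  expect_equal(apply(out, 1, min), rep(0, 5))
  expect_equal(apply(out, 1, max), rep(1, 5))
})

test_that("downsampling interpolates linearly, preserves endpoints and affine signals", {
  ramp <- matrix(seq(0, 1, length.out = 300), 1)
  out <- downsample_segment(ramp, 100)
  expect_equal(dim(out), c(1, 100))
  expect_equal(out[1, 1], 0)
  expect_equal(out[1, 100], 1)
  expect_equal(out[1, ], seq(0, 1, length.out = 100), tolerance = 1e-12)
  m <- matrix(rnorm(5 * 50), 5)
  expect_equal(downsample_segment(m, 50), m, ignore_attr = TRUE)
  expect_message(downsample_segment(m, 60), "upsampling")
})

test_that("continuous windowing cuts exact non-overlapping slices and drops the tail", {
  tr <- matrix(rnorm(5 * 35000), 5)  # 3500 s at 10 Hz
  w <- window_continuous(tr, window_s = 600, sampling_rate = 10)
  expect_length(w, 5)
  expect_true(all(vapply(w, ncol, integer(1)) == 6000))
  expect_identical(w[[2]], tr[, 6001:12000])
  expect_length(window_continuous(tr[, 1:6000], 600, 10), 1)
  expect_warning(out <- window_continuous(tr[, 1:100], 600, 10), "shorter")
  expect_length(out, 0)
})

test_that("the deep-model composition order is load-bearing", {
  # split -> downsample -> baseline-subtract -> min-max; swapping the last
  # two steps changes the result on a generic segment
  set.seed(4)
  seg <- matrix(rnorm(5 * 300, mean = 2), 5)
  a <- scale_segment(subtract_baseline(downsample_segment(seg, 100)))
  b <- subtract_baseline(scale_segment(downsample_segment(seg, 100)))
  expect_false(isTRUE(all.equal(a, b)))
})
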