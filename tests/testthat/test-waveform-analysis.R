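test_that("beam-on cropping keeps the first contiguous run and rezeroes time", {
  tr <- surrogate_trace(times = seq(0, 0.5, by = 0.1),
                        amplitudes = 1:6,
                        beam_on = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
                        nominal_rate = 10)
  cr <- crop_to_beam_on(tr)
  expect_equal(length(cr), 3L)
  expect_equal(cr$times, c(0, 0.1, 0.2))
  expect_equal(cr$amplitudes, 3:5)
  expect_equal(attr(cr, "time_offset"), 0.2)

  all_on <- fn_trace(sin, 1, 10)
  expect_equal(crop_to_beam_on(all_on)$amplitudes, all_on$amplitudes)

  off <- surrogate_trace(0:2, 1:3, rep(FALSE, 3), nominal_rate = 1)
  expect_error(crop_to_beam_on(off), "synchronization")
})

test_that("resampling is linear and accurate for a band-limited signal", {
  const <- fn_trace(function(t) rep(2.5, length(t)), 2, 38)
  expect_equal(resample_to(const, seq(0.1, 1.9, by = 0.05))$amplitudes,
               rep(2.5, 37))

  ramp <- fn_trace(function(t) 2 * t, 2, 38)
  expect_equal(resample_to(ramp, 0.5)$amplitudes, 1.0, tolerance = 1e-9)

  # 4 s period sine sampled at 38 Hz, downsampled onto the 30 Hz grid:
  # linear interpolation error bounded well below 0.005 of amplitude
  sine <- fn_trace(function(t) sin(2 * pi * t / 4), 60, 38)
  q <- seq(0, 59.9, by = 1 / 30)
  rs <- resample_to(sine, q)
  expect_lt(max(abs(rs$amplitudes - sin(2 * pi * q / 4))), 0.005)

  expect_error(resample_to(ramp, 3), "extrapolation")
})

test_that("end-inhale peaks of a 4 s sine land at the analytic maxima", {
  sine <- fn_trace(function(t) sin(2 * pi * t / 4), 60, 30)
  pk <- detect_end_inhale_peaks(sine)
  expect_length(pk$peak_times, 15L)
  expect_equal(pk$peak_times, seq(1, 57, by = 4), tolerance = 1 / 30)

  ramp <- fn_trace(function(t) t, 30, 30)
  expect_length(detect_end_inhale_peaks(ramp)$peak_times, 0L)
})

test_that("clipped (plateau) tops are reported at the run midpoint", {
  clipped <- fn_trace(function(t) pmin(sin(2 * pi * t / 4), 0.95), 60, 30)
  pk <- detect_end_inhale_peaks(clipped)
  expect_length(pk$peak_times, 15L)
  expect_true(all(pk$peak_kind == "plateau_midpoint"))
  # clip runs are symmetric about the underlying maxima at 1, 5, ..., 57
  expect_equal(pk$peak_times, seq(1, 57, by = 4), tolerance = 1 / 30)
})

test_that("normalization scales the tallest peak to 1 and is idempotent", {
  f <- function(t) ifelse(t < 2, 2, 4) * pmax(sin(2 * pi * t / 4), 0)
  tr <- fn_trace(f, 8, 50)
  pk <- detect_end_inhale_peaks(tr, peak_config(min_separation_s = 1,
                                                smoothing_s = 0))
  nn <- normalize_to_max_peak(tr, pk)
  peak_amp <- sapply(pk$peak_times,
                     function(pt) nn$amplitudes[which.min(abs(nn$times - pt))])
  expect_equal(max(peak_amp), 1, tolerance = 1e-3)
  again <- normalize_to_max_peak(nn, detect_end_inhale_peaks(
    nn, peak_config(min_separation_s = 1, smoothing_s = 0)))
  expect_equal(again$amplitudes, nn$amplitudes, tolerance = 1e-9)
  # normalization never changes peak times
  pk2 <- detect_end_inhale_peaks(nn, peak_config(min_separation_s = 1,
                                                 smoothing_s = 0))
  expect_equal(pk2$peak_times, pk$peak_times)

  zero <- fn_trace(function(t) rep(0, length(t)), 2, 10)
  expect_error(normalize_to_max_peak(
    zero, structure(list(peak_times = 1, peak_kind = "sharp"),
                    class = "peak_list")),
    "normalization")
  expect_error(normalize_to_max_peak(tr, detect_end_inhale_peaks(
    fn_trace(function(t) t, 2, 10))), "empty peak list")
})

test_that("peak pairing is greedy nearest-neighbour with an offset cap", {
  a <- c(1, 5, 9)
  p0 <- pair_peaks(a, a, max_offset_s = 1)
  expect_equal(p0$time_b - p0$time_a, rep(0, 3))

  p1 <- pair_peaks(a, a + 0.1, max_offset_s = 1)
  expect_equal(p1$time_b - p1$time_a, rep(0.1, 3), tolerance = 1e-9)

  # extra mid-cycle peak in a stays unmatched (enumerated 3-vs-2 case)
  p2 <- pair_peaks(c(1, 3, 5), c(1.05, 5.02), max_offset_s = 1)
  expect_equal(nrow(p2), 2L)
  expect_equal(attr(p2, "n_unmatched_a"), 1L)
  expect_equal(attr(p2, "n_unmatched_b"), 0L)
  expect_equal(p2$time_a, c(1, 5))

  expect_equal(nrow(pair_peaks(numeric(0), a, 1)), 0L)
})

test_that("latency summaries follow the stated sign convention", {
  # rpm (channel a) peaks 100 ms before bellows everywhere
  a <- seq(1, 41, by = 4)
  p <- pair_peaks(a, a + 0.1, max_offset_s = 1)
  ls <- latency_summary(p)
  expect_equal(ls$mean_ms, 100, tolerance = 1e-9)
  expect_equal(ls$sd_ms, 0, tolerance = 1e-9)

  # symmetric deltas: mean 0, two-point sample sd |x1 - x2| / sqrt(2)
  p2 <- data.frame(time_a = c(1, 5), time_b = c(1 - 0.05, 5 + 0.05))
  ls2 <- latency_summary(p2)
  expect_equal(ls2$mean_ms, 0, tolerance = 1e-9)
  expect_equal(ls2$sd_ms, 100 / sqrt(2), tolerance = 1e-6)

  # direct binning enumeration: deltas {10, 20, 30}, 20 ms bins
  p3 <- data.frame(time_a = c(1, 5, 9),
                   time_b = c(1.01, 5.02, 9.03))
  ls3 <- latency_summary(p3, hist_bin_ms = 20)
  expect_equal(ls3$histogram$count, c(2L, 1L))
  expect_equal(ls3$histogram$bin_left, c(0, 20))
  expect_equal(sum(ls3$histogram$count), 3L)

  expect_error(latency_summary(data.frame(time_a = numeric(0),
                                          time_b = numeric(0))),
               "insufficient")
})

test_that("trace statistics: CV definition and breaths per minute", {
  tr <- fn_trace(function(t) sin(2 * pi * t / 4), 60, 30)
  pk <- detect_end_inhale_peaks(tr)
  st <- trace_stats(tr, pk)
  expect_equal(st$cv_percent, st$sd_amp / st$mean_amp * 100)
  expect_equal(st$bpm, 15, tolerance = 0.01)

  const <- fn_trace(function(t) rep(3, length(t)), 10, 10)
  stc <- trace_stats(const, detect_end_inhale_peaks(const))
  expect_equal(stc$sd_amp, 0)
  expect_equal(stc$cv_percent, 0)

  zero_mean <- fn_trace(function(t) rep(0, length(t)), 10, 10)
  expect_error(trace_stats(zero_mean, detect_end_inhale_peaks(zero_mean)),
               "CV undefined")
})

test_that("pearson_r is exact on affine relations and validates input", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 3), -1)
  # invariance under positive-slope affine maps of either argument
  y <- c(2, 1, 7, 3, 9)
  expect_equal(pearson_r(3 * x + 10, y), pearson_r(x, y))
  expect_equal(pearson_r(x, 0.5 * y - 4), pearson_r(x, y))
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("Mann-Whitney U matches hand-computed small cases", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-9)
  expect_identical(res$method, "exact")

  # identical two-point samples: midranks give U = n_x n_y / 2
  res2 <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(res2$U, 2)

  # swapping the samples maps U -> n_x n_y - U at equal p
  x <- c(3.2, 1.5, 7.8, 2.2); y <- c(4.4, 0.9, 6.1)
  r1 <- mann_whitney_u(x, y); r2 <- mann_whitney_u(y, x)
  expect_equal(r1$U + r2$U, length(x) * length(y))
  expect_equal(r1$p_value, r2$p_value)

  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("synthetic lag injection is recovered with the documented sign", {
  # delaying the bellows channel must increase the mean latency
  base <- make_pair(seed = 7, lag_ms = 0)
  lag <- make_pair(seed = 7, lag_ms = 80)
  m0 <- compare_waveforms_report(base$rpm, base$bellows)$latency$mean_ms
  m1 <- compare_waveforms_report(lag$rpm, lag$bellows)$latency$mean_ms
  expect_gt(m1, m0)
  expect_equal(m1 - m0, 80, tolerance = 25)
})
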