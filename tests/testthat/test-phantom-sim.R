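test_that("regular breathing curves peak at exactly the programmed amplitude", {
  prog <- make_breathing_curve("regular", list(amplitude_cm = 1,
                                               period_s = 4,
                                               duration_s = 40))
  at_peaks <- prog$si_cm[prog$times %in% seq(0, 40, by = 4)]
  expect_equal(at_peaks, rep(1, length(at_peaks)), tolerance = 1e-9)
  expect_true(all(prog$si_cm >= -1e-12))
  expect_equal(prog$ap_cm, 0.3 * prog$si_cm)
})

test_that("generators are bit-reproducible for a fixed seed", {
  a <- make_breathing_curve("irregular", seed = 11)
  b <- make_breathing_curve("irregular", seed = 11)
  expect_identical(a, b)
  c <- make_breathing_curve("irregular", seed = 12)
  expect_false(identical(a$si_cm, c$si_cm))

  pr <- make_breathing_curve("regular", list(duration_s = 30))
  s1 <- synthesize_surrogates(pr, seed = 5)
  s2 <- synthesize_surrogates(pr, seed = 5)
  expect_identical(s1, s2)
})

test_that("lognormal amplitude jitter reproduces the requested CV", {
  prog <- make_breathing_curve("irregular",
                               list(amplitude_jitter_pct = 30,
                                    duration_s = 820, period_s = 4),
                               seed = 42)
  amps <- prog$cycle_amplitudes_cm
  expect_gt(length(amps), 180L)
  cv <- stats::sd(amps) / mean(amps) * 100
  expect_gt(cv, 20)
  expect_lt(cv, 40)
})

test_that("out-of-range amplitudes warn without aborting", {
  expect_warning(make_breathing_curve("regular", list(amplitude_cm = 4,
                                                      duration_s = 10)),
                 "0.5-3 cm")
})

test_that("surrogate channels reproduce the shared driving signal", {
  prog <- make_breathing_curve("regular", list(duration_s = 40))
  tr <- synthesize_surrogates(prog, seed = 3)
  expect_identical(tr$rpm$label, "rpm")
  expect_identical(tr$bellows$label, "bellows")
  # identical wall-clock rising edge of X-RAY ON
  t_on_r <- tr$rpm$times[which(tr$rpm$beam_on)[1]]
  t_on_b <- tr$bellows$times[which(tr$bellows$beam_on)[1]]
  expect_equal(t_on_r, t_on_b)
  # zero noise, zero lag: normalized channels agree at common timestamps
  wf <- compare_waveforms_report(tr$rpm, tr$bellows)
  expect_lt(max(abs(wf$rpm$amplitudes - wf$bellows$amplitudes)), 0.01)
  expect_gt(wf$pearson_r, 0.999)
})

test_that("a plateau floor clamps bellows minima while rpm varies", {
  prog <- make_breathing_curve("irregular", list(duration_s = 40),
                               seed = 9)
  tr <- synthesize_surrogates(
    prog,
    bellows_model = surrogate_model(gain = 2.5, sampling_rate_hz = 38,
                                    plateau_floor = 0.1),
    seed = 9)
  expect_gte(min(tr$bellows$amplitudes), 0.1)
  expect_lt(min(tr$rpm$amplitudes), 0.1 * 10 / 2.5)

  expect_error(synthesize_surrogates(
    prog, rpm_model = surrogate_model(lag_ms = 60000)), "lag")
})

test_that("sphere voxelization matches the analytic volume within 2%", {
  ph <- build_phantom(dim_vox = c(40, 40, 40), spacing_mm = c(1, 1, 1),
                      inserts = list(list(shape = "sphere",
                                          center_mm = c(20, 20, 20),
                                          size_mm = 30, hu = 50)))
  vol_cc <- sum(ph$data == 50) * 1 / 1000
  expect_equal(vol_cc, 4 / 3 * pi * 1.5^3, tolerance = 0.02)

  empty <- build_phantom(dim_vox = c(10, 10, 10), inserts = list())
  expect_true(all(empty$data == -800))

  expect_error(build_phantom(spacing_mm = c(0, 1, 1)), "spacing")
  expect_error(build_phantom(dim_vox = c(10, 10, 10),
                             spacing_mm = c(1, 1, 1),
                             inserts = list(list(shape = "sphere",
                                                 center_mm = c(5, 5, 9),
                                                 size_mm = 6, hu = 0))),
               "geometry")
})

test_that("helical acquisition kinematics behave as configured", {
  ph <- build_phantom(dim_vox = c(8, 8, 16), spacing_mm = c(4, 4, 2.5))
  static <- make_breathing_curve("regular", list(amplitude_cm = 0.5,
                                                 duration_s = 200))
  static$si_cm[] <- 0
  cfg <- acquisition_config(rotation_period_s = 0.5, couch_pitch = 0.1,
                            detector_width_mm = 20)
  recs <- simulate_acquisition(ph, static, cfg)
  # no motion: all slices at one couch position are identical
  z0 <- recs[[1]]$couch_z
  px <- lapply(Filter(function(r) r$couch_z == z0, recs), `[[`, "pixels")
  expect_true(all(vapply(px, identical, logical(1), px[[1]])))

  # halving the pitch doubles the records per couch position
  cfg2 <- acquisition_config(rotation_period_s = 0.5, couch_pitch = 0.05,
                             detector_width_mm = 20)
  recs2 <- simulate_acquisition(ph, static, cfg2)
  n1 <- sum(vapply(recs, function(r) r$couch_z == z0, logical(1)))
  n2 <- sum(vapply(recs2, function(r) r$couch_z == z0, logical(1)))
  expect_equal(n2, 2L * n1, tolerance = 0.1)

  short <- make_breathing_curve("regular", list(duration_s = 5))
  expect_error(simulate_acquisition(ph, short, cfg), "coverage")
})

test_that("moving-object slices sweep the programmed excursion in z", {
  ph <- build_phantom(dim_vox = c(8, 8, 30), spacing_mm = c(4, 4, 2.5),
                      inserts = list(list(shape = "sphere",
                                          center_mm = c(16, 16, 37.5),
                                          size_mm = 20, hu = 50)))
  prog <- make_breathing_curve("regular", list(amplitude_cm = 1,
                                               duration_s = 200))
  # recentre the cycle so displacement spans [-0.5, +0.5] cm
  prog$si_cm <- prog$si_cm - 0.5
  cfg <- acquisition_config(rotation_period_s = 0.4, couch_pitch = 0.06,
                            detector_width_mm = 20)
  recs <- simulate_acquisition(ph, prog, cfg)
  zs_obj <- unique(vapply(Filter(function(r) any(r$pixels == 50), recs),
                          `[[`, numeric(1), "couch_z"))
  span_moving <- diff(range(zs_obj))
  span_static <- 20  # sphere diameter, mm
  expect_gt(span_moving, span_static + 10 - 2 * 2.5)  # +-0.5 cm sweep
})

test_that("ground-truth ITV is the EI/EE/MID union with the right limits", {
  ph <- build_phantom(dim_vox = c(24, 24, 100), spacing_mm = c(1, 1, 1),
                      inserts = list(list(shape = "sphere",
                                          center_mm = c(12, 12, 30),
                                          size_mm = 12, hu = 50)))
  # zero amplitude: the union collapses onto the static object
  flat <- make_breathing_curve("regular", list(amplitude_cm = 0.5,
                                               duration_s = 10))
  flat$si_cm[] <- 0
  itv0 <- ground_truth_itv(ph, flat)
  expect_equal(itv0$data, phantom_object_mask(ph)$data)

  # EI - EE > 4r: three disjoint spheres
  wide <- make_breathing_curve("regular", list(amplitude_cm = 3,
                                               duration_s = 10))
  itv3 <- ground_truth_itv(ph, wide)
  expect_equal(mask_volume(itv3), 3 * mask_volume(itv0), tolerance = 0.02)

  # monotone non-decreasing in excursion amplitude
  vols <- vapply(c(0.5, 1, 1.5, 2), function(a) {
    pr <- make_breathing_curve("regular", list(amplitude_cm = a,
                                               duration_s = 10))
    mask_volume(ground_truth_itv(ph, pr))
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("the eight study cases span regular to erratic breathing", {
  p1 <- study_program_params(1)
  p8 <- study_program_params(8)
  expect_lt(p1$amplitude_jitter_pct, p8$amplitude_jitter_pct)
  expect_true(all(vapply(1:8, function(i) {
    pp <- study_program_params(i)
    pp$amplitude_cm >= 0.5 && pp$amplitude_cm <= 3
  }, logical(1))))
  expect_error(study_program_params(9))
})
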