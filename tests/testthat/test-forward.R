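test_that("weight function has the anisotropic point-source form", {
  cst <- model_constants()
  r <- 80
  # closed form at z = 0: 1 / (4 pi sigma_r sqrt(K) r)
  expect_equal(weight_function(r, 0, cst),
               1 / (4 * pi * cst$sigma_r * sqrt(cst$K) * (r / 1000)))
  # even in z
  z <- c(0.1, 0.5, 2, 10)
  expect_equal(weight_function(r, z, cst), weight_function(r, -z, cst))
  # 1/r scaling on the fiber-normal axis
  expect_equal(weight_function(2 * r, 0, cst) / weight_function(r, 0, cst),
               0.5)
  # strictly decreasing in |z| and in r
  expect_true(all(diff(weight_function(r, seq(0, 5, 0.5), cst)) < 0))
  w_r <- vapply(c(50, 100, 200, 400), weight_function,
                numeric(1), axial_mm = 0.3, constants = cst)
  expect_true(all(diff(w_r) < 0))
  expect_error(weight_function(0, 0, cst), "singular")
})

test_that("intracellular action potential has the Rosenfalck shape", {
  # canonical axial scale: peak at z = 3 mm with value 96*27*exp(-3) - 90
  cst1 <- model_constants(iap_scale_per_mm = 1)
  expect_equal(intracellular_action_potential(0, cst1), -90)
  expect_equal(intracellular_action_potential(-5, cst1), -90)
  expect_equal(intracellular_action_potential(3, cst1),
               96 * 27 * exp(-3) - 90)   # ~ 39.05 mV
  expect_equal(intracellular_action_potential(1e3, cst1), -90)
  # single depolarization peak, at 3 / lambda for any axial scale
  cst <- model_constants()
  z <- seq(0.01, 20, by = 0.01)
  e <- intracellular_action_potential(z, cst)
  expect_equal(z[which.max(e)], 3 / cst$iap_scale_per_mm, tolerance = 5e-3)
  expect_equal(max(e), 96 * 27 * exp(-3) - 90, tolerance = 1e-4)
  expect_equal(sum(diff(e) > 0 & c(diff(e)[-1], -1) <= 0), 1)
})

test_that("transmembrane current scales with diameter squared and is balanced", {
  cst <- model_constants()
  z <- seq(0.05, 25, by = 0.05)
  i50 <- transmembrane_current(z, 50, cst)
  i25 <- transmembrane_current(z, 25, cst)
  expect_equal(i50, 4 * i25)
  # balanced source: integral of a second derivative of a flat-tailed profile
  zz <- seq(-5, 40, by = 0.001)
  expect_lt(abs(sum(transmembrane_current(zz, 50, cst)) * 0.001),
            1e-6 * max(abs(i50)))
  cst2 <- cst; cst2$current_scale <- 2 * cst$current_scale
  expect_equal(transmembrane_current(z, 50, cst2), 2 * i50)
  expect_error(transmembrane_current(z, 0, cst), "positive")
})

test_that("simulated SFP is triphasic with physical polarity", {
  w <- simulate_sfp(fiber_scenario(55, 80))
  y <- w$samples_mv
  expect_gt(max(y), 0)
  expect_lt(min(y), 0)
  # positive-negative-positive: max before min before trailing positive phase
  expect_lt(which.max(y), which.min(y))
  expect_gt(max(y[which.min(y):length(y)]), 0)
  f <- sfp_features(w)
  expect_false(f$polyphasic)
  expect_equal(f$n_zero_crossings, 2)
})

test_that("waveform scales linearly with the source gain, durations do not", {
  cst <- model_constants()
  cst2 <- cst; cst2$current_scale <- 2 * cst$current_scale
  w1 <- simulate_sfp(fiber_scenario(45, 120), cst)
  w2 <- simulate_sfp(fiber_scenario(45, 120), cst2)
  expect_equal(measure_amplitude(w2), 2 * measure_amplitude(w1))
  expect_equal(measure_negative_peak_duration(w2),
               measure_negative_peak_duration(w1))
})

test_that("durations scale inversely with conduction velocity", {
  # the source profile is fixed in the axial coordinate, so the waveform in
  # time is a pure 1/v stretch: tz(d1) * v(d1) = tz(d2) * v(d2) at fixed r
  r <- 150
  tzv <- vapply(c(30, 55, 85), function(d) {
    w <- simulate_sfp(fiber_scenario(d, r))
    as.numeric(measure_negative_peak_duration(w)) * conduction_velocity(d)
  }, numeric(1))
  expect_equal(tzv[1], tzv[2], tolerance = 1e-3)
  expect_equal(tzv[2], tzv[3], tolerance = 1e-3)
})

test_that("features converge under sampling refinement", {
  w2 <- simulate_sfp(fiber_scenario(55, 80), dt_ms = 0.002)
  w1 <- simulate_sfp(fiber_scenario(55, 80), dt_ms = 0.001)
  expect_lt(abs(measure_amplitude(w2) - measure_amplitude(w1)) /
              measure_amplitude(w1), 0.001)
  expect_lt(abs(as.numeric(measure_negative_peak_duration(w2)) -
                  as.numeric(measure_negative_peak_duration(w1))), 0.004)
})

test_that("too-coarse sampling is rejected", {
  expect_error(simulate_sfp(fiber_scenario(55, 80), dt_ms = 0.1),
               "too coarse")
})

test_that("waveforms round-trip through CSV and JSON", {
  w <- simulate_sfp(fiber_scenario(60, 200), dt_ms = 0.01)
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_waveform_csv(w, fc)
  wc <- read_waveform_csv(fc)
  expect_equal(wc$samples_mv, w$samples_mv)
  expect_equal(wc$dt_ms, w$dt_ms, tolerance = 1e-9)
  write_waveform_json(w, fj)
  wj <- read_waveform_json(fj)
  expect_equal(wj$samples_mv, w$samples_mv)
  expect_equal(wj$t0_ms, w$t0_ms)
})

test_that("decimation to clinical sampling changes tz by at most one interval", {
  w <- simulate_sfp(fiber_scenario(55, 80))
  w25 <- decimate_waveform(w, 0.04)
  expect_equal(w25$dt_ms, 0.04)
  expect_lt(abs(as.numeric(measure_negative_peak_duration(w25)) -
                  as.numeric(measure_negative_peak_duration(w))), 0.04)
  expect_error(decimate_waveform(w, 0.005), "integer multiple")
})
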