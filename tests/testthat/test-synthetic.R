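test_that("identical seeds reproduce bit-identical simulations", {
  truth <- synthetic_truth(31.4, 60, 44, 0.75, 37)
  a <- generate_capillary_trace(truth, 1, seed = 42)
  b <- generate_capillary_trace(truth, 1, seed = 42)
  expect_identical(a$trace$off_counts, b$trace$off_counts)
  expect_identical(a$trace$on_phase_intensity, b$trace$on_phase_intensity)
  expect_identical(a$events, b$events)
  c <- generate_capillary_trace(truth, 1, seed = 43)
  expect_false(identical(a$trace$off_counts, c$trace$off_counts))

  la <- generate_linescan(truth, 2, seed = 7)
  lb <- generate_linescan(truth, 2, seed = 7)
  expect_identical(la$image$pixels, lb$image$pixels)
})

test_that("the default sensor model shifts right as temperature drops", {
  m <- sensor_model()
  for (tau in seq(10, 35, length.out = 10)) {
    po2_cold <- (1 / tau - 1 / m$tau0_us(32.4)) / m$kq(32.4)
    po2_warm <- (1 / tau - 1 / m$tau0_us(37.0)) / m$kq(37.0)
    expect_gt(po2_cold, po2_warm)
  }
})

test_that("noiseless calibration sweeps lie exactly on the model curve", {
  m <- sensor_model()
  pts <- generate_calibration_dataset(m, 35.7, noise_frac = 0)
  expect_equal(pts$lifetime_us, sensor_tau(m, pts$po2_mmHg, 35.7))
  # default schedule sweeps air saturation down to a few mmHg
  expect_equal(max(pts$po2_mmHg), 159)
  expect_equal(min(pts$po2_mmHg), 2)
  expect_error(generate_calibration_dataset(m, 37, po2_schedule = c(200, 50)),
               "within")
})

test_that("decay-simulation calibration mode accumulates decays per Po2 step", {
  m <- sensor_model()
  pts <- generate_calibration_dataset(m, 37, po2_schedule = c(159, 100, 50, 2),
                                      seed = 3, n_decays = 30000)
  tau_true <- sensor_tau(m, pts$po2_mmHg, 37)
  expect_lt(max(abs(pts$lifetime_us - tau_true) / tau_true), 0.02)
})

test_that("zero flux yields a constant trace without events", {
  truth <- synthetic_truth(42, 42, 0, 0.5, 37)
  sim <- generate_capillary_trace(truth, 0.5, seed = 1, poisson_noise = FALSE)
  expect_equal(nrow(sim$events), 0)
  expect_equal(unique(sim$po2_true_mmHg), 42)
  expect_equal(length(unique(sim$trace$on_phase_intensity)), 1)
})

test_that("planted event counts are renewal-consistent and exactly detectable", {
  truth <- synthetic_truth(31.4, 60, 44, 0.75, 37)
  sim <- generate_capillary_trace(truth, 10, seed = 37, poisson_noise = FALSE)
  n <- nrow(sim$events)
  # renewal count: mean 440, sd ~ sqrt(440/3); accept +/- 5 sd
  expect_lt(abs(n - 440), 5 * sqrt(440 / 3))
  ev <- detect_rbc_passages(sim$trace$on_phase_intensity,
                            sim$trace$cycle_start_ms)
  expect_equal(nrow(ev), n)
  expect_equal(rbc_flux(ev, 10), n / 10)
})

test_that("inconsistent ground truth is rejected", {
  expect_error(synthetic_truth(40, 30, 44, 0.75, 37), "eat_peak")
  expect_error(generate_capillary_trace(
    synthetic_truth(31.4, 60, 44, 0.75, 37), 0.2), "at least 0.5")
})

test_that("presets carry the documented condition values", {
  dry <- preset("awake_dry_37C")
  expect_equal(dry$flux_per_s, 44)
  expect_equal(dry$velocity_mm_s, 0.75)
  expect_equal(dry$po2_inter_mmHg, 31.4)
  expect_equal(dry$temperature_c, 37.0)
  expect_equal(dry$po2_mean_target_mmHg, 42)
  cool <- preset("awake_cool_34C")
  expect_equal(cool$velocity_mm_s, 0.5)
  expect_equal(cool$flux_per_s, 35)
  expect_equal(cool$temperature_c, 34.2)
  expect_equal(cool$po2_mean_target_mmHg, 34)
  an <- preset("anesth_cool_32C")
  expect_equal(an$po2_mean_target_mmHg, 65)
  expect_equal(an$temperature_c, 32.4)
  expect_error(preset("awake_warm"), "available")
})

test_that("preset EAT peaks are calibrated to the planted Po2 Mean target", {
  # the bisection promises the noise-free all-cycle fit-then-convert Po2
  # equals the target within 0.5 mmHg
  m <- sensor_model()
  for (nm in c("awake_dry_37C", "awake_cool_34C")) {
    tr <- preset(nm)
    sim <- generate_capillary_trace(tr, 4, model = m, seed = 1,
                                    poisson_noise = FALSE)
    fit <- fit_lifetime(accumulate_decay(sim$trace), conf = FALSE)
    po2 <- po2_from_tau(sensor_true_curve(m, tr$temperature_c), fit$tau_us)
    expect_lt(abs(po2 - tr$po2_mean_target_mmHg), 0.5)
    expect_gte(tr$eat_peak_mmHg, tr$po2_inter_mmHg)
  }
})
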