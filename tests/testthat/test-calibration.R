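test_that("noiseless Stern-Volmer points are inverted exactly", {
  po2 <- c(0, 40, 80, 120, 159)
  tau <- 1 / (1 / 40 + 1.0e-3 * po2)
  cv <- fit_calibration_curve(
    data.frame(lifetime_us = tau, po2_mmHg = po2), 37)
  expect_lt(abs(cv$tau0_us - 40) / 40, 1e-9)
  expect_lt(abs(cv$kq_per_us_mmHg - 1e-3) / 1e-3, 1e-9)
  expect_equal(cv$valid_po2_range, c(0, 159))
  expect_lt(cv$fit_residual, 1e-9)
})

test_that("noisy calibration recovers parameters and matches the grid oracle", {
  po2 <- c(0, 40, 80, 120, 159)
  tau_true <- 1 / (1 / 40 + 1.0e-3 * po2)
  for (seed in 1:5) {
    set.seed(seed)
    tau <- tau_true * (1 + 0.01 * rnorm(length(tau_true)))
    cv <- fit_calibration_curve(
      data.frame(lifetime_us = tau, po2_mmHg = po2), 37)
    expect_lt(abs(cv$tau0_us - 40) / 40, 0.05)
    expect_lt(abs(cv$kq_per_us_mmHg - 1e-3) / 1e-3, 0.05)
    oracle <- grid_fit_calibration(tau, po2)
    expect_lt(abs(cv$tau0_us - oracle$tau0_us) / oracle$tau0_us, 0.005)
    expect_lt(abs(cv$kq_per_us_mmHg - oracle$kq_per_us_mmHg) /
                oracle$kq_per_us_mmHg, 0.005)
  }
})

test_that("fit preconditions and data-quality warnings are enforced", {
  po2 <- c(0, 40, 80, 120)
  tau <- 1 / (1 / 40 + 1e-3 * po2)
  df <- data.frame(lifetime_us = tau, po2_mmHg = po2)
  expect_error(fit_calibration_curve(df[1:3, ], 37), "at least 4")
  expect_error(fit_calibration_curve(
    data.frame(lifetime_us = tau, po2_mmHg = po2 / 10), 37), "span")
  # shuffled lifetimes destroy monotonicity -> recorded warning
  set.seed(1)
  df_bad <- data.frame(lifetime_us = sample(tau), po2_mmHg = po2)
  expect_warning(cv <- fit_calibration_curve(df_bad, 37), "monoton")
  expect_gt(length(cv$warnings), 0)
})

test_that("default synthetic calibration runs cover the four bath temperatures", {
  cs <- synthetic_calibration_set()
  expect_equal(cs$temperatures_c, c(32.4, 34.2, 35.7, 37.0))
  expect_length(cs$curves, 4)
})

test_that("forward evaluation follows the quenching relation", {
  cv <- fit_calibration_curve(data.frame(
    lifetime_us = 1 / (1 / 40 + 1e-3 * c(0, 50, 100, 159)),
    po2_mmHg = c(0, 50, 100, 159)), 37)
  expect_equal(tau_from_po2(cv, 0), 40, tolerance = 1e-9)
  expect_equal(tau_from_po2(cv, 50), 1 / (0.025 + 0.05), tolerance = 1e-9)
  grid <- seq(0, 159, length.out = 100)
  expect_true(all(diff(tau_from_po2(cv, grid)) < 0))
  expect_lt(tau_from_po2(cv, 1e6), 0.01)
  expect_error(tau_from_po2(cv, -1), "non-negative")
})

test_that("lifetime-to-Po2 inversion is exact and range-guarded", {
  cs <- synthetic_calibration_set()
  # roundtrip identity at the resting capillary Po2
  tau42 <- tau_from_po2(interpolate_curve(cs, 37), 42)
  expect_equal(po2_from_tau(cs, tau42, 37), 42, tolerance = 1e-9)
  # roundtrip over a Po2 grid
  cv <- interpolate_curve(cs, 35.7)
  for (p in seq(0, 159, length.out = 25)) {
    expect_lt(abs(po2_from_tau(cs, tau_from_po2(cv, p), 35.7) - p), 1e-6)
  }
  # tau0 maps to zero oxygen
  expect_equal(po2_from_tau(cs, cv$tau0_us, 35.7), 0)
  # hard errors: temperature and lifetime out of range
  expect_error(po2_from_tau(cs, 20, 45), "temperature")
  expect_error(po2_from_tau(cs, 500, 37), "admissible interval")
  expect_error(po2_from_tau(cs, 0.5, 37), "admissible interval")
})

test_that("temperature interpolation is linear with node identity", {
  cs <- synthetic_calibration_set()
  # stored node returned unchanged
  expect_identical(interpolate_curve(cs, 34.2), cs$curves[[2]])
  # midpoint parameters are arithmetic means of the bracketing curves
  mid <- (35.7 + 37.0) / 2
  cv <- interpolate_curve(cs, mid)
  expect_equal(cv$tau0_us,
               (cs$curves[[3]]$tau0_us + cs$curves[[4]]$tau0_us) / 2)
  expect_equal(cv$kq_per_us_mmHg,
               (cs$curves[[3]]$kq_per_us_mmHg + cs$curves[[4]]$kq_per_us_mmHg) / 2)
  # monotone node parameters give a monotone interpolant between nodes
  taus <- vapply(seq(32.4, 37.0, length.out = 30),
                 function(tc) interpolate_curve(cs, tc)$tau0_us, numeric(1))
  expect_true(all(diff(taus) < 0))
  # capped extrapolation: within 0.5 C uses the edge curve, beyond errors
  expect_equal(interpolate_curve(cs, 37.4)$tau0_us, cs$curves[[4]]$tau0_us)
  expect_error(interpolate_curve(cs, 38.0), "outside admissible")
})

test_that("lower temperature implies higher Po2 at fixed lifetime (right shift)", {
  cs <- synthetic_calibration_set()
  for (tau in seq(12, 30, length.out = 8)) {
    expect_gt(po2_from_tau(cs, tau, 32.4), po2_from_tau(cs, tau, 37.0))
  }
})

test_that("temperature-mismatched conversion biases Po2 downward when assuming warmer", {
  model <- default_model()
  cs <- synthetic_calibration_set()
  # noiseless constant-Po2 trace acquired at 34.2 C
  truth <- synthetic_truth(34, 34, flux_per_s = 0, velocity_mm_s = 0.5,
                           temperature_c = 34.2)
  sim <- generate_capillary_trace(truth, 1, model = model, seed = 4,
                                  poisson_noise = FALSE)
  matched <- po2_mean_from_trace(sim$trace, cs, 34.2, conf = FALSE)$po2_mmHg
  wrong <- po2_mean_from_trace(sim$trace, cs, 37.0, conf = FALSE)$po2_mmHg
  expect_lt(abs(matched - 34), 0.5)   # matched curve: unbiased
  expect_lt(wrong, matched)           # warmer curve: Po2 underestimated
})
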