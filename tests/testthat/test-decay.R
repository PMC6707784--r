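test_that("a one-second stream segments into 4000 cycles", {
  g <- gate_config()
  trace <- segment_cycles(numeric(1.25e6), g)
  expect_equal(trace$n_cycles, 4000)
  # spacing equals the nominal cycle period
  expect_equal(unique(round(diff(trace$cycle_start_ms), 9)), 0.25)
})

test_that("a partial trailing cycle is dropped with a warning", {
  g <- gate_config()
  expect_warning(trace <- segment_cycles(numeric(469), g), "partial cycle")
  expect_equal(trace$n_cycles, 1)
  expect_error(segment_cycles(numeric(0), g), "empty")
  expect_error(segment_cycles(numeric(100), g), "shorter than one")
})

test_that("segmentation reproduces the generator's planted per-cycle totals", {
  truth <- synthetic_truth(31.4, 60, 44, 0.75, 37)
  sim <- generate_capillary_trace(truth, 0.6, seed = 9)
  stream <- trace_to_stream(sim$trace)
  seg <- suppressWarnings(segment_cycles(stream, sim$trace$gate))
  expect_equal(seg$n_cycles, sim$trace$n_cycles)
  expect_equal(seg$on_phase_intensity, sim$trace$on_phase_intensity)
  expect_equal(unname(seg$off_counts), unname(sim$trace$off_counts))
})

test_that("decay accumulation applies the dead-time rule and is additive", {
  truth <- synthetic_truth(40, 40, 0, 0.5, 37)
  sim <- generate_capillary_trace(truth, 0.5, seed = 2)
  trace <- sim$trace
  g <- trace$gate

  # 5.6 us at 0.8 us bins: exactly 7 leading bins discarded
  expect_equal(g$n_discard_bins, ceiling(5.6 / 0.8))
  d <- accumulate_decay(trace, 1)
  expect_equal(length(d$time_us), g$n_bins_off - 7)
  expect_gte(d$time_us[1], 5.6)
  # single-cycle selection returns that cycle's trimmed bins unchanged
  expect_equal(d$counts, unname(trace$off_counts[1, -(1:7)]))

  # additivity over disjoint selections
  a <- accumulate_decay(trace, 1:100)
  b <- accumulate_decay(trace, 101:250)
  u <- accumulate_decay(trace, 1:250)
  expect_equal(a$counts + b$counts, u$counts)
  expect_equal(u$n_cycles_averaged, 250)
  # permutation invariance
  p <- accumulate_decay(trace, sample(1:250))
  expect_equal(p$counts, u$counts)

  expect_error(accumulate_decay(trace, integer(0)), "empty")
  expect_error(accumulate_decay(trace, trace$n_cycles + 1), "out of range")
})

test_that("a noiseless exponential decay is fitted to machine accuracy", {
  d <- make_decay(5000, tau_us = 20, dark_rate = 0, poisson_noise = FALSE)
  f <- fit_lifetime(d)
  expect_lt(abs(f$tau_us - 20) / 20, 1e-6)
  expect_lt(f$background, 1e-6)
})

test_that("Poisson-noisy lifetime fits agree with the brute-force MLE oracle", {
  for (seed in c(11, 12)) {
    d <- make_decay(60000, tau_us = 25, seed = seed)
    f <- fit_lifetime(d)
    expect_lt(abs(f$tau_us - 25) / 25, 0.01)
    oracle <- grid_fit_lifetime(d$time_us, d$counts)
    expect_lt(abs(f$tau_us - oracle$tau_us) / oracle$tau_us, 0.005)
  }
})

test_that("flat or empty decays never yield a confident lifetime", {
  g <- gate_config()
  keep <- seq(g$n_discard_bins + 1, g$n_bins_off)
  t_bins <- g$off_bin_centers_us[keep]
  set.seed(5)
  flat <- structure(list(time_us = t_bins,
                         counts = rpois(length(t_bins), 50),
                         n_cycles_averaged = 1000, bin_us = g$bin_us),
                    class = "decay_curve")
  res <- try(fit_lifetime(flat), silent = TRUE)
  if (!inherits(res, "try-error")) {
    expect_false(res$identifiable)
    expect_false(is.finite(res$ci95_us))
  }
  zero <- structure(list(time_us = t_bins, counts = numeric(length(t_bins)),
                         n_cycles_averaged = 1, bin_us = g$bin_us),
                    class = "decay_curve")
  expect_error(fit_lifetime(zero), "all-zero")
  short <- structure(list(time_us = t_bins[1:5], counts = rep(1, 5),
                          n_cycles_averaged = 1, bin_us = g$bin_us),
                     class = "decay_curve")
  expect_error(fit_lifetime(short), "at least 10")
})

test_that("lifetime bias and confidence width shrink as cycles accumulate", {
  sizes <- c(1e3, 1e4, 1e5)
  bias <- ci <- matrix(NA, 10, length(sizes))
  for (s in 1:10) {
    for (j in seq_along(sizes)) {
      f <- fit_lifetime(make_decay(sizes[j], tau_us = 18, seed = 100 * s + j))
      bias[s, j] <- abs(f$tau_us - 18)
      ci[s, j] <- f$ci95_us
    }
  }
  expect_true(all(diff(colMeans(bias)) < 0))
  expect_true(all(diff(colMeans(ci)) < 0))
})

test_that("Po2 Mean is fit-then-convert and exact at zero oxygen", {
  cs <- synthetic_calibration_set()
  truth0 <- synthetic_truth(0, 0, 0, 0.5, 37)
  sim0 <- generate_capillary_trace(truth0, 0.5, seed = 3, poisson_noise = FALSE)
  out <- po2_mean_from_trace(sim0$trace, cs, 37, conf = FALSE)
  expect_equal(out$fit$tau_us, 40, tolerance = 1e-5)
  expect_equal(out$po2_mmHg, 0, tolerance = 1e-3)

  # on EAT-modulated traces, fit-then-convert differs from converting the
  # per-cycle lifetimes and averaging the Po2 values
  truth <- synthetic_truth(31.4, 70, 44, 0.75, 37)
  sim <- generate_capillary_trace(truth, 2, seed = 6, poisson_noise = FALSE)
  ftc <- po2_mean_from_trace(sim$trace, cs, 37, conf = FALSE)$po2_mmHg
  cta <- mean(vapply(sim$tau_true_us, function(tt) po2_from_tau(cs, tt, 37),
                     numeric(1)))
  expect_gt(abs(ftc - cta), 0.5)
})

test_that("Po2 Mean recovers a planted constant 42 mmHg within 2 mmHg", {
  cs <- synthetic_calibration_set()
  truth <- synthetic_truth(42, 42, 0, 0.75, 37)
  sim <- generate_capillary_trace(truth, 10, seed = 8)   # 40,000 decays
  out <- po2_mean_from_trace(sim$trace, cs, 37)
  expect_lt(abs(out$po2_mmHg - 42), 2)
  expect_true(is.finite(out$fit$ci95_us))
})
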