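# build a minimal trace with given cycle times and flat photon content;
# classification only looks at cycle_start_ms and the gate
flat_trace <- function(duration_ms, gate = gate_config()) {
  n <- floor(duration_ms * 1000 / gate$cycle_period_us)
  t_ms <- (seq_len(n) - 1) * gate$cycle_period_us / 1000
  photon_trace(t_ms, rep(1, n), matrix(0L, n, gate$n_bins_off), gate)
}

events_df <- function(entry, exit) {
  structure(data.frame(entry_ms = entry, exit_ms = exit,
                       trough_intensity = rep(NA_real_, length(entry))),
            class = c("rbc_events", "data.frame"))
}

test_that("noiseless passages are detected exactly with sub-cycle edges", {
  truth <- preset("awake_dry_37C")
  sim <- generate_capillary_trace(truth, 1.0, seed = 3, poisson_noise = FALSE)
  ev <- detect_rbc_passages(sim$trace$on_phase_intensity,
                            sim$trace$cycle_start_ms)
  expect_equal(nrow(ev), nrow(sim$events))
  expect_lt(max(abs(ev$entry_ms - sim$events$entry_ms)), 0.25 + 1e-9)
  # exits compared only for events wholly inside the recorded span (the
  # last passage may overhang the end of the trace)
  whole <- sim$events$exit_ms <= max(sim$trace$cycle_start_ms)
  expect_lt(max(abs(ev$exit_ms[whole] - sim$events$exit_ms[whole])),
            0.25 + 1e-9)
})

test_that("a constant-intensity trace yields no events, with a warning", {
  t_ms <- (0:999) * 0.25
  expect_warning(
    ev <- detect_rbc_passages(rep(150, 1000), t_ms), "dynamic range")
  expect_equal(nrow(ev), 0)
  expect_error(detect_rbc_passages(rep(150, 50), t_ms[1:50]), "at least 100")
})

test_that("shot-noise detection keeps recall and precision above 0.95", {
  truth <- synthetic_truth(31.4, 60, flux_per_s = 40, velocity_mm_s = 0.75,
                           temperature_c = 37)
  sim <- generate_capillary_trace(truth, 5, seed = 13)
  ev <- detect_rbc_passages(sim$trace$on_phase_intensity,
                            sim$trace$cycle_start_ms)
  m <- match_events(ev, sim$events)
  expect_gte(m["recall"], 0.95)
  expect_gte(m["precision"], 0.95)
})

test_that("classification windows follow the border and mid-gap rules", {
  w <- eat_windows()
  trace <- flat_trace(60)
  # two events with a 20 ms gap: inter window 13 ms, border flanks 2.5 ms
  ev <- events_df(c(10, 34), c(14, 38))
  cls <- classify_cycles(ev, trace, w)
  t <- trace$cycle_start_ms
  inter_t <- t[cls$labels == "inter_rbc"]
  expect_equal(min(inter_t), 17.5, tolerance = 0.25)
  expect_equal(max(inter_t), 30.5, tolerance = 0.25)
  expect_equal(diff(range(inter_t)), 13, tolerance = 0.5)
  border_t <- t[cls$labels == "border"]
  d_edge <- vapply(border_t, function(x) min(abs(x - c(10, 14, 34, 38))),
                   numeric(1))
  expect_true(all(d_edge >= 1.0 & d_edge <= 3.5))
  # each flank pools 2.5 ms of cycles on each side of the gap edges
  expect_equal(sum(border_t > 14 & border_t < 24), 10, tolerance = 1)

  # an 8 ms gap (< 2*3.5 + 5) holds no inter-RBC cycles
  ev2 <- events_df(c(10, 22), c(14, 26))
  cls2 <- classify_cycles(ev2, trace, w)
  gap_cycles <- t > 14 & t < 22
  expect_equal(sum(cls2$labels[gap_cycles] == "inter_rbc"), 0)
})

test_that("labels partition the cycles with compliant windows", {
  truth <- preset("awake_dry_37C")
  sim <- generate_capillary_trace(truth, 5, seed = 17)
  ev <- detect_rbc_passages(sim$trace$on_phase_intensity,
                            sim$trace$cycle_start_ms)
  cls <- classify_cycles(ev, sim$trace)
  # exactly one label per cycle
  expect_equal(length(cls$labels), sim$trace$n_cycles)
  expect_false(anyNA(cls$labels))
  t <- sim$trace$cycle_start_ms
  edges <- c(ev$entry_ms, ev$exit_ms)
  # border compliance vs the detected edges
  d_border <- vapply(t[cls$labels == "border"],
                     function(x) min(abs(x - edges)), numeric(1))
  expect_true(all(d_border >= 1.0 - 1e-9 & d_border <= 3.5 + 1e-9))
  # inter windows at least 5 ms long (up to one cycle of discretisation)
  runs <- rle(as.character(cls$labels))
  inter_spans <- runs$lengths[runs$values == "inter_rbc"] * 0.25
  expect_true(all(inter_spans >= 5.0 - 0.25))
})

test_that("pooled Po2 recovers the planted tissue baseline and the floor rule", {
  cs <- synthetic_calibration_set()
  truth <- synthetic_truth(31.4, 48, 44, 0.75, 37)
  sim <- generate_capillary_trace(truth, 10, seed = 19)
  ev <- detect_rbc_passages(sim$trace$on_phase_intensity,
                            sim$trace$cycle_start_ms)
  cls <- classify_cycles(ev, sim$trace)
  inter <- po2_pool(cls, "inter_rbc", cs, 37)
  expect_lt(abs(inter$po2_mmHg - 31.4), 2)
  # "all" pool is exactly the Po2 Mean contract
  all_pool <- po2_pool(cls, "all", cs, 37, conf = FALSE)
  expect_equal(all_pool$po2_mmHg,
               po2_mean_from_trace(sim$trace, cs, 37, conf = FALSE)$po2_mmHg)
  # pool floor: a starved pool errors with its size
  expect_error(po2_pool(cls, "border", cs, 37, pool_floor = 1e6),
               "below the floor")
})

test_that("RBC flux is the event count rate", {
  ev44 <- events_df(seq(1, 990, length.out = 44),
                    seq(1, 990, length.out = 44) + 4)
  expect_equal(rbc_flux(ev44, 1.0), 44.0)
  expect_equal(rbc_flux(events_df(numeric(0), numeric(0)), 2), 0.0)
  ev33 <- events_df(seq_len(33), seq_len(33) + 0.5)
  expect_equal(rbc_flux(ev33, 1.5), 22.0)
  expect_error(rbc_flux(ev33, 0), "positive")
})

test_that("the EAT profile peaks at the RBC edge and flattens without EATs", {
  cs <- synthetic_calibration_set()
  truth <- synthetic_truth(31.4, 60, 44, 0.75, 37)
  sim <- generate_capillary_trace(truth, 10, seed = 23)
  prof <- eat_profile(sim$events, sim$trace, cs, 37)
  expect_gt(nrow(prof), 3)
  # the bin at the RBC edge carries the profile maximum (bins inside the
  # RBC share the planted peak Po2, so compare within fit noise)
  edge <- which.min(abs(prof$offset_ms))
  expect_gt(prof$po2_mmHg[edge], 0.95 * max(prof$po2_mmHg))
  # Po2 relaxes monotonically away from the RBC on the plasma side
  plasma <- prof[prof$offset_ms > 0, ]
  expect_lt(plasma$po2_mmHg[nrow(plasma)], prof$po2_mmHg[edge] - 5)
  # far-offset bins beyond every half-gap are omitted
  expect_true(all(prof$offset_ms <= 10))

  flat <- synthetic_truth(42, 42, 44, 0.75, 37)
  simf <- generate_capillary_trace(flat, 10, seed = 29)
  proff <- eat_profile(simf$events, simf$trace, cs, 37, pool_floor = 2000)
  expect_lt(diff(range(proff$po2_mmHg)), 2.5)

  expect_error(eat_profile(sim$events[1:5, ], sim$trace, cs, 37),
               "at least 10")
})
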