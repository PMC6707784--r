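#' Analyze one gated capillary acquisition
#'
#' Runs the full per-capillary pipeline on a gated trace: RBC detection from
#' the on-phase fluorescence, cycle classification relative to the detected
#' passages, pooled fit-then-convert Po2 for the all-cycle ("Po2 Mean"),
#' RBC-border ("Po2 RBC") and mid-gap ("Po2 InterRBC") pools, Hill-equation
#' saturation from Po2 RBC, and RBC flux. Conversion uses the calibration
#' curve matched (or interpolated) to `temperature_c`; a temperature outside
#' the calibration set's admissible range is a hard error, since converting
#' with a wrong-temperature curve silently corrupts Po2.
#'
#' @param trace A [photon_trace()].
#' @param set A [calibration_set()].
#' @param temperature_c Sensor temperature during acquisition, Celsius.
#' @param windows An [eat_windows()].
#' @param hill A [hill_parameters()].
#' @param pool_floor Minimum cycles per Po2 pool.
#' @param velocity_mm_s Optional velocity from [estimate_velocity()].
#' @param capillary_id,condition_label,capillary_diameter_um Metadata copied
#'   into the result.
#' @param detect_args List of overrides for [detect_rbc_passages()].
#' @return List of class `capillary_analysis`: `result` (a
#'   [capillary_result()] row), `events`, `classification`, `fits` (the
#'   three `lifetime_fit`s), `pool_sizes`.
#' @export
analyze_capillary <- function(trace, set, temperature_c,
                              windows = eat_windows(),
                              hill = hill_parameters(),
                              pool_floor = 500,
                              velocity_mm_s = NA_real_,
                              capillary_id = "cap1",
                              condition_label = "unlabeled",
                              capillary_diameter_um = NA_real_,
                              detect_args = list()) {
  .check_set_temperature(set, temperature_c)
  events <- do.call(detect_rbc_passages,
                    c(list(on_intensity = trace$on_phase_intensity,
                           cycle_times_ms = trace$cycle_start_ms),
                      detect_args))
  cls <- classify_cycles(events, trace, windows)
  duration_s <- trace$n_cycles * trace$gate$cycle_period_us / 1e6

  p_mean <- po2_pool(cls, "all", set, temperature_c, pool_floor = pool_floor)
  p_rbc <- po2_pool(cls, "border", set, temperature_c, pool_floor = pool_floor)
  p_inter <- po2_pool(cls, "inter_rbc", set, temperature_c,
                      pool_floor = pool_floor)

  res <- capillary_result(
    capillary_id = capillary_id,
    condition_label = condition_label,
    po2_mean_mmHg = p_mean$po2_mmHg,
    po2_rbc_mmHg = p_rbc$po2_mmHg,
    po2_inter_rbc_mmHg = p_inter$po2_mmHg,
    so2_fraction = so2_from_po2(p_rbc$po2_mmHg, hill),
    rbc_flux_per_s = rbc_flux(events, duration_s),
    velocity_mm_s = velocity_mm_s,
    temperature_c = temperature_c,
    capillary_diameter_um = capillary_diameter_um
  )
  structure(list(
    result = res,
    events = events,
    classification = cls,
    fits = list(mean = p_mean$fit, border = p_rbc$fit, inter = p_inter$fit),
    pool_sizes = c(all = p_mean$n_cycles, border = p_rbc$n_cycles,
                   inter_rbc = p_inter$n_cycles)
  ), class = "capillary_analysis")
}

#' @export
print.capillary_analysis <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<capillary_analysis> %s (%s): Po2 mean %.1f / RBC %.1f / inter %.1f mmHg, SO2 %.2f, %.1f RBC/s\n",
    r$capillary_id, r$condition_label, r$po2_mean_mmHg, r$po2_rbc_mmHg,
    r$po2_inter_rbc_mmHg, r$so2_fraction, r$rbc_flux_per_s))
  invisible(x)
}

#' Simulate and analyze one capillary end to end
#'
#' Convenience wrapper for recovery experiments: simulates a gated trace
#' (and optionally a line scan) from a ground-truth preset, then analyzes
#' it with the matched-temperature calibration.
#'
#' @param truth A [synthetic_truth()].
#' @param set A [calibration_set()].
#' @param duration_s Trace duration, seconds.
#' @param seed RNG seed.
#' @param model Sensor model for the simulation.
#' @param with_velocity Also simulate a line scan and estimate velocity?
#' @param linescan_duration_s Line-scan duration, seconds.
#' @param temperature_c Conversion temperature (defaults to the truth's;
#'   override to study temperature-mismatch bias).
#' @param ... Passed to [analyze_capillary()].
#' @return A `capillary_analysis` (see [analyze_capillary()]), with the
#'   simulation stored as `sim`.
#' @export
simulate_and_analyze <- function(truth, set, duration_s = 10, seed = truth$seed,
                                 model = sensor_model(), with_velocity = TRUE,
                                 linescan_duration_s = 12,
                                 temperature_c = truth$temperature_c, ...) {
  sim <- generate_capillary_trace(truth, duration_s, model = model, seed = seed)
  vel <- NA_real_
  if (with_velocity) {
    ls <- generate_linescan(truth, duration_s = linescan_duration_s,
                            seed = seed + 10000L)
    vel <- estimate_velocity(ls$image)$velocity_mm_s
  }
  out <- analyze_capillary(sim$trace, set, temperature_c,
                           velocity_mm_s = vel, ...)
  out$sim <- sim
  out
}
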