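#' Synthetic temperature-dependent oxygen sensor model
#'
#' Ground-truth model of the phosphorescent sensor used by the simulators:
#' Stern-Volmer quenching with zero-oxygen lifetime `tau0(T)` and quenching
#' constant `kq(T)` varying linearly with temperature. The default
#' magnitudes are synthetic (chosen to be representative of a Pt-porphyrin
#' probe); the asserted physical property is the direction of the
#' temperature effect: at fixed lifetime, a colder sensor implies a higher
#' Po2 (the calibration curve "shifts right" as temperature drops).
#'
#' @param tau0_lo_us,tau0_hi_us Zero-oxygen lifetime at `t_lo_c` / `t_hi_c`.
#' @param kq_lo,kq_hi Quenching constant (1/(us*mmHg)) at `t_lo_c` / `t_hi_c`.
#' @param t_lo_c,t_hi_c Anchor temperatures, Celsius.
#' @return Object of class `sensor_model` with functions `tau0_us(T)` and
#'   `kq(T)`.
#' @export
#' @examples
#' m <- sensor_model()
#' sensor_tau(m, po2_mmHg = 42, temperature_c = 37)
sensor_model <- function(tau0_lo_us = 45, tau0_hi_us = 40,
                         kq_lo = 0.90e-3, kq_hi = 1.00e-3,
                         t_lo_c = 32.4, t_hi_c = 37.0) {
  stopifnot(tau0_lo_us > 0, tau0_hi_us > 0, kq_lo > 0, kq_hi > 0,
            t_hi_c > t_lo_c)
  lin <- function(y_lo, y_hi) {
    force(y_lo); force(y_hi)
    function(temperature_c) {
      y_lo + (y_hi - y_lo) * (temperature_c - t_lo_c) / (t_hi_c - t_lo_c)
    }
  }
  structure(list(
    tau0_us = lin(tau0_lo_us, tau0_hi_us),
    kq = lin(kq_lo, kq_hi),
    t_lo_c = t_lo_c,
    t_hi_c = t_hi_c
  ), class = "sensor_model")
}

#' True sensor lifetime at a given Po2 and temperature
#'
#' @param model A [sensor_model()].
#' @param po2_mmHg Oxygen partial pressure(s), mmHg.
#' @param temperature_c Temperature, Celsius.
#' @return Lifetime(s), microseconds.
#' @export
sensor_tau <- function(model, po2_mmHg, temperature_c) {
  stopifnot(inherits(model, "sensor_model"))
  if (any(po2_mmHg < 0)) stop("po2 must be non-negative")
  1 / (1 / model$tau0_us(temperature_c) + model$kq(temperature_c) * po2_mmHg)
}

#' Exact calibration curve implied by the sensor model
#'
#' Convenience for simulations: the `calibration_curve` whose parameters are
#' the model's true `tau0(T)` and `kq(T)` (no fitting, no noise).
#'
#' @param model A [sensor_model()].
#' @param temperature_c Temperature, Celsius.
#' @param po2_range Valid Po2 range recorded on the curve, mmHg.
#' @return A `calibration_curve`.
#' @export
sensor_true_curve <- function(model, temperature_c, po2_range = c(0, 159)) {
  structure(list(
    temperature_c = temperature_c,
    tau0_us = model$tau0_us(temperature_c),
    kq_per_us_mmHg = model$kq(temperature_c),
    fit_residual = 0,
    valid_po2_range = po2_range,
    warnings = character(0)
  ), class = "calibration_curve")
}

#' Generate one synthetic calibration run
#'
#' Emulates a calibration-chamber sweep: Po2 is stepped down from air
#' saturation (159 mmHg) to a few mmHg while the lifetime is measured at a
#' controlled temperature. Two noise modes: multiplicative Gaussian noise of
#' `noise_frac` on the true lifetime (fast), or — when `n_decays` is given —
#' full decay simulation in which each Po2 step accumulates `n_decays`
#' Poisson photon decays and the lifetime is extracted with
#' [fit_lifetime()].
#'
#' @param model A [sensor_model()].
#' @param temperature_c Bath temperature, Celsius.
#' @param po2_schedule Descending Po2 schedule within [0, 159] mmHg; default
#'   sweeps 159 to 2 mmHg in 20 steps.
#' @param noise_frac Multiplicative lifetime noise fraction (ignored in
#'   decay-simulation mode).
#' @param seed RNG seed.
#' @param n_decays If non-NULL, number of accumulated decays per Po2 value
#'   (the acquisition collects 30,000 per point).
#' @param gate,photon_rate Gate configuration and per-bin gate-end photon
#'   rate for decay-simulation mode.
#' @return Data frame of calibration points: `lifetime_us`, `po2_mmHg`,
#'   `temperature_c`.
#' @export
generate_calibration_dataset <- function(model, temperature_c,
                                         po2_schedule = seq(159, 2,
                                                            length.out = 20),
                                         noise_frac = 0.01, seed = 1,
                                         n_decays = NULL,
                                         gate = gate_config(),
                                         photon_rate = 0.3) {
  stopifnot(inherits(model, "sensor_model"))
  if (any(po2_schedule < 0 | po2_schedule > 159)) {
    stop("po2_schedule must lie within [0, 159] mmHg")
  }
  tau_true <- sensor_tau(model, po2_schedule, temperature_c)
  set.seed(seed)
  if (is.null(n_decays)) {
    tau <- tau_true * (1 + noise_frac * stats::rnorm(length(tau_true)))
  } else {
    keep <- seq.int(gate$n_discard_bins + 1, gate$n_bins_off)
    t_bins <- gate$off_bin_centers_us[keep]
    tau <- vapply(tau_true, function(tt) {
      mu <- n_decays * photon_rate * exp(-t_bins / tt)
      dc <- structure(list(time_us = t_bins,
                           counts = stats::rpois(length(mu), mu),
                           n_cycles_averaged = n_decays,
                           bin_us = gate$bin_us), class = "decay_curve")
      fit_lifetime(dc, conf = FALSE)$tau_us
    }, numeric(1))
  }
  data.frame(lifetime_us = tau, po2_mmHg = po2_schedule,
             temperature_c = temperature_c)
}

#' Fit the default four-temperature synthetic calibration set
#'
#' Generates one calibration run per temperature from the sensor model and
#' fits a Stern-Volmer curve to each, mirroring the four bath temperatures
#' at which the sensor is calibrated (32.4, 34.2, 35.7, 37.0 C).
#'
#' @param model A [sensor_model()].
#' @param temperatures_c Calibration temperatures, Celsius.
#' @param noise_frac Lifetime noise per run (0 = exact model curves).
#' @param seed RNG seed (each run derives its own sub-seed).
#' @return A [calibration_set()].
#' @export
synthetic_calibration_set <- function(model = sensor_model(),
                                      temperatures_c = c(32.4, 34.2, 35.7, 37.0),
                                      noise_frac = 0, seed = 1) {
  curves <- lapply(seq_along(temperatures_c), function(i) {
    pts <- generate_calibration_dataset(model, temperatures_c[i],
                                        noise_frac = noise_frac,
                                        seed = seed + i)
    fit_calibration_curve(pts, temperatures_c[i])
  })
  calibration_set(curves)
}
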