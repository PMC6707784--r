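#' Fit a Stern-Volmer calibration curve at one temperature
#'
#' Oxygen quenches the phosphorescence of the PtP-C343 sensor following the
#' Stern-Volmer relation `1/tau = 1/tau0 + kq * Po2`, which is linear in
#' inverse lifetime. The fit is ordinary least squares of `1/tau` on Po2
#' (uniform weights), giving the zero-oxygen lifetime `tau0` and the
#' quenching constant `kq` in closed form and making the curve invertible
#' exactly.
#'
#' @param points Data frame with columns `lifetime_us` and `po2_mmHg`
#'   (optionally `temperature_c`, which must then match `temperature_c`).
#' @param temperature_c Bath temperature of the run, Celsius.
#' @return Object of class `calibration_curve`: `temperature_c`, `tau0_us`,
#'   `kq_per_us_mmHg`, `fit_residual` (RMS lifetime residual, us),
#'   `valid_po2_range`, `warnings` (character vector; non-monotone input is
#'   recorded here).
#' @export
#' @examples
#' pts <- generate_calibration_dataset(sensor_model(), 37, noise_frac = 0)
#' fit_calibration_curve(pts, 37)
fit_calibration_curve <- function(points, temperature_c) {
  stopifnot(is.data.frame(points),
            all(c("lifetime_us", "po2_mmHg") %in% names(points)))
  if (nrow(points) < 4) {
    stop("need at least 4 calibration points (2-parameter fit)")
  }
  if (diff(range(points$po2_mmHg)) < 50) {
    stop("calibration points must span at least 50 mmHg of Po2")
  }
  if (any(points$lifetime_us <= 0)) stop("lifetimes must be positive")
  if (any(points$po2_mmHg < 0 | points$po2_mmHg > 200)) {
    stop("Po2 values must lie in [0, 200] mmHg")
  }
  if ("temperature_c" %in% names(points) &&
      any(abs(points$temperature_c - temperature_c) > 1e-6)) {
    stop("points carry a temperature differing from `temperature_c`")
  }

  warns <- character(0)
  rho <- suppressWarnings(
    stats::cor(points$po2_mmHg, points$lifetime_us, method = "spearman"))
  if (is.na(rho) || rho > -0.9) {
    warns <- c(warns, sprintf(
      "lifetime not monotonically decreasing in Po2 (spearman rho = %.2f)", rho))
    warning(warns[length(warns)])
  }

  inv_tau <- 1 / points$lifetime_us
  fit <- stats::lm(inv_tau ~ points$po2_mmHg)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(intercept) || intercept <= 0 || !is.finite(slope) || slope <= 0) {
    stop("non-physical Stern-Volmer fit (tau0 or kq not positive)")
  }
  pred_tau <- 1 / (intercept + slope * points$po2_mmHg)
  structure(list(
    temperature_c = temperature_c,
    tau0_us = 1 / intercept,
    kq_per_us_mmHg = slope,
    fit_residual = sqrt(mean((points$lifetime_us - pred_tau)^2)),
    valid_po2_range = range(points$po2_mmHg),
    warnings = warns
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> T = %.1f C: tau0 = %.3f us, kq = %.4g /(us*mmHg), Po2 %g-%g mmHg\n",
    x$temperature_c, x$tau0_us, x$kq_per_us_mmHg,
    x$valid_po2_range[1], x$valid_po2_range[2]))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' Forward-evaluate a calibration curve
#'
#' `tau = 1 / (1/tau0 + kq * po2)`; strictly decreasing in Po2.
#'
#' @param curve A `calibration_curve`.
#' @param po2_mmHg Oxygen partial pressure(s), mmHg; must be non-negative.
#' @return Lifetime(s) in microseconds.
#' @export
tau_from_po2 <- function(curve, po2_mmHg) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(po2_mmHg < 0)) stop("po2 must be non-negative")
  1 / (1 / curve$tau0_us + curve$kq_per_us_mmHg * po2_mmHg)
}

#' Bundle calibration curves measured at several temperatures
#'
#' @param curves List of `calibration_curve` objects at distinct
#'   temperatures (any order; stored sorted by temperature).
#' @param interpolation_policy Currently only `"linear"` (parameters
#'   interpolated linearly in temperature between bracketing curves).
#' @return Object of class `calibration_set`.
#' @export
calibration_set <- function(curves, interpolation_policy = "linear") {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "calibration_curve")))
  temps <- vapply(curves, `[[`, numeric(1), "temperature_c")
  if (anyDuplicated(temps)) stop("curve temperatures must be distinct")
  curves <- curves[order(temps)]
  structure(list(
    curves = curves,
    temperatures_c = sort(temps),
    interpolation_policy = match.arg(interpolation_policy, "linear")
  ), class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d curves at %s C\n",
              length(x$curves),
              paste(format(x$temperatures_c), collapse = ", ")))
  invisible(x)
}

# admissible temperature range: node range extended by +/- 0.5 C
.check_set_temperature <- function(set, temperature_c, margin = 0.5) {
  lo <- min(set$temperatures_c) - margin
  hi <- max(set$temperatures_c) + margin
  if (temperature_c < lo || temperature_c > hi) {
    stop(sprintf(
      "temperature %.2f C outside admissible calibration range [%.2f, %.2f] C",
      temperature_c, lo, hi))
  }
}

#' Temperature-interpolate a calibration curve
#'
#' Returns the curve applicable at `temperature_c`: the stored curve when the
#' temperature matches a node exactly, otherwise `tau0` and `kq` linearly
#' interpolated between the bracketing curves. Up to 0.5 C beyond the node
#' range the nearest node curve is used (capped extrapolation); beyond that
#' an error is raised rather than silently extrapolating.
#'
#' @param set A [calibration_set()].
#' @param temperature_c Target temperature, Celsius.
#' @return A `calibration_curve`.
#' @export
interpolate_curve <- function(set, temperature_c) {
  stopifnot(inherits(set, "calibration_set"))
  .check_set_temperature(set, temperature_c)
  temps <- set$temperatures_c
  j <- which(abs(temps - temperature_c) < 1e-9)
  if (length(j) == 1) return(set$curves[[j]])
  if (temperature_c < temps[1]) return(set$curves[[1]])
  if (temperature_c > temps[length(temps)]) return(set$curves[[length(temps)]])
  i <- findInterval(temperature_c, temps)
  a <- set$curves[[i]]; b <- set$curves[[i + 1]]
  w <- (temperature_c - temps[i]) / (temps[i + 1] - temps[i])
  structure(list(
    temperature_c = temperature_c,
    tau0_us = (1 - w) * a$tau0_us + w * b$tau0_us,
    kq_per_us_mmHg = (1 - w) * a$kq_per_us_mmHg + w * b$kq_per_us_mmHg,
    fit_residual = (1 - w) * a$fit_residual + w * b$fit_residual,
    valid_po2_range = c(max(a$valid_po2_range[1], b$valid_po2_range[1]),
                        min(a$valid_po2_range[2], b$valid_po2_range[2])),
    warnings = character(0)
  ), class = "calibration_curve")
}

#' Convert a lifetime to Po2 through the temperature-matched curve
#'
#' Exact inverse of [tau_from_po2()] on the curve selected (or interpolated)
#' for the given temperature: `po2 = (1/tau - 1/tau0) / kq`. The lifetime
#' must lie within the lifetime range implied by the curve's valid Po2
#' range, extended by `range_tol_frac` of that range; using the wrong
#' temperature's curve is the central error mode this interface guards
#' against, so out-of-range temperatures are a hard error.
#'
#' @param set A [calibration_set()] (or a single `calibration_curve`, in
#'   which case `temperature_c` is ignored).
#' @param tau_us Measured lifetime(s), microseconds.
#' @param temperature_c Sensor temperature, Celsius.
#' @param range_tol_frac Fractional tolerance on the admissible lifetime
#'   range (default 2%).
#' @return Po2 in mmHg (clamped at 0 when `tau` marginally exceeds `tau0`
#'   within the tolerance).
#' @export
po2_from_tau <- function(set, tau_us, temperature_c = NULL,
                         range_tol_frac = 0.02) {
  curve <- if (inherits(set, "calibration_curve")) {
    set
  } else {
    stopifnot(inherits(set, "calibration_set"))
    interpolate_curve(set, temperature_c)
  }
  tau_hi <- curve$tau0_us
  tau_lo <- tau_from_po2(curve, curve$valid_po2_range[2])
  tol <- range_tol_frac * (tau_hi - tau_lo)
  bad <- tau_us < tau_lo - tol | tau_us > tau_hi + tol
  if (any(bad)) {
    stop(sprintf(
      "lifetime %.3f us outside admissible interval [%.3f, %.3f] us (+/- %.3f us tolerance) for the %.1f C curve",
      tau_us[which(bad)[1]], tau_lo, tau_hi, tol, curve$temperature_c))
  }
  pmax(0, (1 / tau_us - 1 / curve$tau0_us) / curve$kq_per_us_mmHg)
}
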