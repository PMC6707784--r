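#' Accumulate phosphorescence decays over selected cycles
#'
#' Sums off-phase photon counts bin-wise across the selected cycles and
#' applies the dead-time rule: every bin starting less than
#' `discard_after_gate_us` (5.6 us by default) after the end of the AOM gate
#' is removed before lifetime fitting. With 0.8 us bins this drops the first
#' 7 bins.
#'
#' @param trace A [photon_trace()].
#' @param cycle_indices Cycles to pool (default: all). Must be non-empty and
#'   within range.
#' @return Object of class `decay_curve` with fields `time_us` (bin centers
#'   relative to gate end, post-discard), `counts`, `n_cycles_averaged`.
#' @export
accumulate_decay <- function(trace, cycle_indices = seq_len(trace$n_cycles)) {
  if (length(cycle_indices) == 0) stop("empty cycle selection")
  if (any(cycle_indices < 1) || any(cycle_indices > trace$n_cycles)) {
    stop("cycle_indices out of range")
  }
  gate <- trace$gate
  counts <- colSums(trace$off_counts[cycle_indices, , drop = FALSE])
  keep <- seq.int(gate$n_discard_bins + 1, gate$n_bins_off)
  structure(list(
    time_us = gate$off_bin_centers_us[keep],
    counts = counts[keep],
    n_cycles_averaged = length(cycle_indices),
    bin_us = gate$bin_us
  ), class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d bins (%.1f-%.1f us), %.0f photons over %d cycles\n",
              length(x$time_us), min(x$time_us), max(x$time_us),
              sum(x$counts), x$n_cycles_averaged))
  invisible(x)
}

# Poisson negative log-likelihood for counts ~ Poisson(A exp(-t/tau) + B),
# dropping the data-only lgamma term (irrelevant for optimisation and for
# likelihood-ratio differences).
.decay_nll <- function(par, t, counts) {
  mu <- par[2] * exp(-t / par[1]) + par[3] + 1e-12
  sum(mu - counts * log(mu))
}

# Profile the likelihood over (A, B) at fixed tau.
.decay_nll_profile <- function(tau, t, counts, start) {
  fn <- function(p) .decay_nll(c(tau, p), t, counts)
  o <- stats::optim(pmax(start, c(1e-9, 0)), fn, method = "L-BFGS-B",
                    lower = c(1e-12, 0), upper = c(Inf, Inf))
  o$value
}

#' Fit a single-exponential lifetime to an accumulated decay
#'
#' Maximum-likelihood fit of `counts ~ Poisson(A * exp(-t/tau) + B)` over the
#' post-discard bins, the standard photon-counting noise model for gated
#' phosphorescence decays. Initialisation is by log-linear regression on
#' background-subtracted counts; the 95% confidence half-width on `tau` comes
#' from the profile likelihood (deviance = 3.84 crossings).
#'
#' @param decay A `decay_curve` from [accumulate_decay()].
#' @param tau_range Search interval for the lifetime, microseconds.
#' @param conf Compute the profile-likelihood confidence interval? Skipping
#'   it (`FALSE`) saves time in bulk runs.
#' @return Object of class `lifetime_fit`: `tau_us`, `amplitude` (counts per
#'   bin at gate end), `background` (counts per bin), `ci95_us` (half-width;
#'   `Inf` when the decay is not identifiable, e.g. flat background),
#'   `n_photons`.
#' @export
fit_lifetime <- function(decay, tau_range = c(0.8, 400), conf = TRUE) {
  t <- decay$time_us
  counts <- decay$counts
  if (length(t) < 10) stop("need at least 10 post-discard bins")
  if (any(counts < 0)) stop("negative counts")
  n_photons <- sum(counts)
  if (n_photons <= 0) stop("all-zero decay: no photons to fit")

  # --- initialisation: tail background estimate + weighted log-linear fit
  n_tail <- max(5L, round(0.15 * length(t)))
  b0 <- mean(utils::tail(counts, n_tail))
  cs <- counts - b0
  pos <- cs > 0
  tau0 <- 20; a0 <- max(counts[1] - b0, 1e-6)
  if (sum(pos) >= 3) {
    fit0 <- stats::lm(log(cs[pos]) ~ t[pos], weights = cs[pos])
    sl <- stats::coef(fit0)[2]
    if (is.finite(sl) && sl < 0) {
      tau0 <- min(max(-1 / sl, tau_range[1]), tau_range[2])
      a0 <- exp(stats::coef(fit0)[1])
    }
  }
  start <- c(tau0, max(a0, 1e-6), max(b0, 1e-6))

  o <- stats::optim(start, .decay_nll, t = t, counts = counts,
                    method = "L-BFGS-B",
                    lower = c(tau_range[1], 1e-12, 0),
                    upper = c(tau_range[2], Inf, Inf),
                    control = list(factr = 10, maxit = 500))
  if (o$convergence != 0) {
    stop(sprintf(
      "lifetime fit did not converge (code %d); best point tau=%.4g A=%.4g B=%.4g",
      o$convergence, o$par[1], o$par[2], o$par[3]))
  }
  tau_hat <- o$par[1]; a_hat <- o$par[2]; b_hat <- o$par[3]
  nll_min <- o$value

  # Likelihood-ratio check against a flat (background-only) model: if the
  # exponential adds nothing, the lifetime is unidentifiable.
  nll_flat <- .decay_nll(c(1, 0, mean(counts)), t, counts)
  identifiable <- 2 * (nll_flat - nll_min) > stats::qchisq(0.95, df = 2)

  ci95 <- NA_real_
  if (conf) {
    if (!identifiable) {
      ci95 <- Inf
    } else {
      dev <- function(tau) {
        2 * (.decay_nll_profile(tau, t, counts, c(a_hat, b_hat)) - nll_min) - 3.84
      }
      lo <- tau_range[1]; hi <- tau_range[2]; hit <- FALSE
      if (dev(tau_range[1]) > 0) {
        lo <- stats::uniroot(dev, c(tau_range[1], tau_hat), tol = 1e-3)$root
      } else hit <- TRUE
      if (dev(tau_range[2]) > 0) {
        hi <- stats::uniroot(dev, c(tau_hat, tau_range[2]), tol = 1e-3)$root
      } else hit <- TRUE
      ci95 <- if (hit) Inf else (hi - lo) / 2
    }
  }

  structure(list(
    tau_us = tau_hat,
    amplitude = a_hat,
    background = b_hat,
    ci95_us = ci95,
    n_photons = n_photons,
    n_cycles_averaged = decay$n_cycles_averaged,
    identifiable = identifiable
  ), class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("<lifetime_fit> tau = %.3f us (ci95 +/- %.3g), %.0f photons, %d cycles\n",
              x$tau_us, x$ci95_us, x$n_photons, x$n_cycles_averaged))
  invisible(x)
}

#' Capillary-averaged Po2 from a full trace (fit-then-convert)
#'
#' The all-cycle capillary Po2 ("Po2 Mean"): every off-phase decay in the
#' trace is accumulated into one decay curve, a single lifetime is fitted,
#' and that lifetime is converted once through the temperature-matched
#' calibration curve. This fit-then-convert definition is not the same as
#' converting per-cycle lifetimes and averaging Po2; on EAT-modulated traces
#' the two differ.
#'
#' @param trace A [photon_trace()].
#' @param set A [calibration_set()].
#' @param temperature_c Sensor temperature for curve selection, Celsius.
#' @param conf Passed to [fit_lifetime()].
#' @return List with `po2_mmHg` and the `lifetime_fit` (`fit`).
#' @export
po2_mean_from_trace <- function(trace, set, temperature_c, conf = TRUE) {
  fit <- fit_lifetime(accumulate_decay(trace), conf = conf)
  po2 <- po2_from_tau(set, fit$tau_us, temperature_c)
  list(po2_mmHg = po2, fit = fit)
}
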