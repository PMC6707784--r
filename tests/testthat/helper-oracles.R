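# Independent brute-force oracles used to cross-check the package's fits.
# Both work by direct grid search over the objective written out here, with
# iterative grid refinement; they share no code with the implementation.

# Least-squares Stern-Volmer fit by grid search over (tau0, kq), minimizing
# the summed squared inverse-lifetime residuals.
grid_fit_calibration <- function(lifetime_us, po2_mmHg,
                                 tau0_range = c(20, 60),
                                 kq_range = c(2e-4, 2e-3),
                                 n_grid = 41, rounds = 4, shrink = 5) {
  inv_tau <- 1 / lifetime_us
  best <- c(NA, NA)
  for (r in seq_len(rounds)) {
    tau0s <- seq(tau0_range[1], tau0_range[2], length.out = n_grid)
    kqs <- seq(kq_range[1], kq_range[2], length.out = n_grid)
    sse <- outer(tau0s, kqs, Vectorize(function(t0, kq) {
      sum((inv_tau - (1 / t0 + kq * po2_mmHg))^2)
    }))
    ij <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    best <- c(tau0s[ij[1]], kqs[ij[2]])
    half_t <- diff(tau0_range) / shrink / 2
    half_k <- diff(kq_range) / shrink / 2
    tau0_range <- c(max(best[1] - half_t, 1), best[1] + half_t)
    kq_range <- c(max(best[2] - half_k, 1e-6), best[2] + half_k)
  }
  list(tau0_us = best[1], kq_per_us_mmHg = best[2],
       resolution = c(diff(tau0_range) / (n_grid - 1),
                      diff(kq_range) / (n_grid - 1)))
}

# Poisson maximum-likelihood fit of counts ~ A exp(-t/tau) + B by grid
# search over (tau, A, B).
grid_fit_lifetime <- function(time_us, counts,
                              tau_range = c(5, 100), rounds = 5, shrink = 4) {
  a_range <- c(max(counts[1], 1) * 0.2, max(counts[1], 1) * 3)
  b_range <- c(0, 2 * mean(utils::tail(counts, 30)) + 1)
  best <- c(NA, NA, NA)
  for (r in seq_len(rounds)) {
    taus <- seq(tau_range[1], tau_range[2], length.out = 31)
    as <- seq(a_range[1], a_range[2], length.out = 15)
    bs <- seq(b_range[1], b_range[2], length.out = 7)
    best_nll <- Inf
    for (tau in taus) {
      e <- exp(-time_us / tau)
      for (a in as) for (b in bs) {
        mu <- a * e + b + 1e-12
        nll <- sum(mu - counts * log(mu))
        if (nll < best_nll) { best_nll <- nll; best <- c(tau, a, b) }
      }
    }
    half <- c(diff(tau_range), diff(a_range), diff(b_range)) / shrink / 2
    tau_range <- c(max(best[1] - half[1], 0.5), best[1] + half[1])
    a_range <- c(max(best[2] - half[2], 1e-6), best[2] + half[2])
    b_range <- c(max(best[3] - half[3], 0), best[3] + half[3])
  }
  list(tau_us = best[1], amplitude = best[2], background = best[3])
}

# Accumulated decay curve simulated directly: the pooled counts over
# n_cycles identical cycles are Poisson with mean n_cycles * mu(t).
make_decay <- function(n_cycles, tau_us, photon_rate = 0.3, dark_rate = 0.01,
                       gate = gate_config(), seed = NULL,
                       poisson_noise = TRUE) {
  keep <- seq(gate$n_discard_bins + 1, gate$n_bins_off)
  t_bins <- gate$off_bin_centers_us[keep]
  mu <- n_cycles * (photon_rate * exp(-t_bins / tau_us) + dark_rate)
  if (poisson_noise) {
    if (!is.null(seed)) set.seed(seed)
    counts <- stats::rpois(length(mu), mu)
  } else {
    counts <- mu
  }
  structure(list(time_us = t_bins, counts = counts,
                 n_cycles_averaged = n_cycles, bin_us = gate$bin_us),
            class = "decay_curve")
}

# Match detected events to planted ones within a tolerance (ms); returns
# recall and precision.
match_events <- function(detected, planted, tol_ms = 1.0) {
  if (nrow(planted) == 0 || nrow(detected) == 0) {
    return(c(recall = 0, precision = 0))
  }
  hit <- vapply(planted$entry_ms, function(e) {
    any(abs(detected$entry_ms - e) <= tol_ms)
  }, logical(1))
  used <- vapply(detected$entry_ms, function(e) {
    any(abs(planted$entry_ms - e) <= tol_ms)
  }, logical(1))
  c(recall = mean(hit), precision = mean(used))
}

default_model <- function() sensor_model()
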