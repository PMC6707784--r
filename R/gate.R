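#' Gated acquisition configuration
#'
#' Describes one excitation/collection cycle of the gated 2PLM acquisition:
#' the acousto-optic modulator (AOM) is open for `excitation_on_us`
#' (fluorescence, used for RBC detection) and closed for `collection_off_us`
#' (phosphorescence decay), repeating every `cycle_period_us`. Photon counts
#' are binned at the acquisition sampling rate; the first
#' `discard_after_gate_us` after the gate closes are excluded from lifetime
#' fits (gate bleed-through / sensor fluorescence tail).
#'
#' The nominal cycle (250 us at 1.25 MHz) spans 312.5 samples. Internally a
#' cycle carries 312 content bins of 0.8 us (31 on-phase + 281 off-phase);
#' the remaining half-sample is dead time. The deviation from the nominal
#' off-phase duration is below 0.2%.
#'
#' @param cycle_period_us Cycle period in microseconds.
#' @param excitation_on_us AOM-on (excitation) duration, microseconds.
#' @param collection_off_us AOM-off (collection) duration, microseconds.
#' @param discard_after_gate_us Dead-time discarded after the gate closes.
#' @param sampling_rate_hz Photon-counting sampling rate, Hz.
#' @return An object of class `gate_config`.
#' @export
#' @examples
#' g <- gate_config()
#' g$n_bins_off     # 281 off-phase bins of 0.8 us
#' g$n_discard_bins # 7 bins (< 5.6 us) dropped before lifetime fitting
gate_config <- function(cycle_period_us = 250,
                        excitation_on_us = 25,
                        collection_off_us = 225,
                        discard_after_gate_us = 5.6,
                        sampling_rate_hz = 1.25e6) {
  if (excitation_on_us + collection_off_us != cycle_period_us) {
    stop("excitation_on_us + collection_off_us must equal cycle_period_us")
  }
  if (discard_after_gate_us >= collection_off_us) {
    stop("discard_after_gate_us must be shorter than the off phase")
  }
  bin_us <- 1e6 / sampling_rate_hz
  n_on <- floor(excitation_on_us / bin_us)
  n_off <- floor(collection_off_us / bin_us)
  g <- list(
    cycle_period_us = cycle_period_us,
    excitation_on_us = excitation_on_us,
    collection_off_us = collection_off_us,
    discard_after_gate_us = discard_after_gate_us,
    sampling_rate_hz = sampling_rate_hz,
    bin_us = bin_us,
    n_bins_on = n_on,
    n_bins_off = n_off,
    samples_per_cycle = cycle_period_us / bin_us,
    # off-phase bin start/center times, measured from the end of the gate
    off_bin_starts_us = (seq_len(n_off) - 1) * bin_us,
    off_bin_centers_us = (seq_len(n_off) - 0.5) * bin_us,
    n_discard_bins = sum((seq_len(n_off) - 1) * bin_us < discard_after_gate_us)
  )
  class(g) <- "gate_config"
  g
}

#' @export
print.gate_config <- function(x, ...) {
  cat(sprintf(
    "<gate_config> %g us cycle (%g on / %g off), %.2f MHz sampling, %g us bins\n",
    x$cycle_period_us, x$excitation_on_us, x$collection_off_us,
    x$sampling_rate_hz / 1e6, x$bin_us))
  cat(sprintf("  %d off-phase bins; first %d (< %g us) discarded for fits\n",
              x$n_bins_off, x$n_discard_bins, x$discard_after_gate_us))
  invisible(x)
}

#' Per-cycle gated photon data
#'
#' Container for a segmented gated acquisition: per-cycle on-phase
#' fluorescence totals (RBC detection channel) and per-cycle binned
#' off-phase phosphorescence counts.
#'
#' @param cycle_start_ms Strictly increasing cycle start times, ms.
#' @param on_phase_intensity Per-cycle summed on-phase counts.
#' @param off_counts Matrix `n_cycles x n_bins_off` of off-phase counts.
#' @param gate A [gate_config()].
#' @return Object of class `photon_trace` with fields `n_cycles`,
#'   `cycle_start_ms`, `on_phase_intensity`, `off_counts`, `gate`.
#' @export
photon_trace <- function(cycle_start_ms, on_phase_intensity, off_counts, gate) {
  off_counts <- as.matrix(off_counts)
  n <- length(cycle_start_ms)
  stopifnot(length(on_phase_intensity) == n, nrow(off_counts) == n)
  if (ncol(off_counts) != gate$n_bins_off) {
    stop(sprintf("off_counts must have %d columns (one per off-phase bin)",
                 gate$n_bins_off))
  }
  if (n > 1 && any(diff(cycle_start_ms) <= 0)) {
    stop("cycle_start_ms must be strictly increasing")
  }
  if (any(on_phase_intensity < 0) || any(off_counts < 0)) {
    stop("photon counts must be non-negative")
  }
  structure(list(
    n_cycles = n,
    cycle_start_ms = as.numeric(cycle_start_ms),
    on_phase_intensity = as.numeric(on_phase_intensity),
    off_counts = off_counts,
    gate = gate
  ), class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("<photon_trace> %d cycles spanning %.1f ms (%d off-phase bins)\n",
              x$n_cycles, diff(range(x$cycle_start_ms)) +
                x$gate$cycle_period_us / 1000, ncol(x$off_counts)))
  invisible(x)
}

#' Segment a flat sample stream into gated cycles
#'
#' Splits a raw photon-count sample stream (one count per sampling bin)
#' into acquisition cycles. Cycle `i` (0-based) starts at sample
#' `floor(i * samples_per_cycle)`; the first `n_bins_on` samples are summed
#' into the on-phase intensity and the next `n_bins_off` form the off-phase
#' decay bins. A trailing partial cycle is dropped with a warning.
#'
#' @param raw_samples Integer-like vector of per-sample photon counts.
#' @param gate A [gate_config()].
#' @return A [photon_trace()].
#' @export
segment_cycles <- function(raw_samples, gate = gate_config()) {
  n_samples <- length(raw_samples)
  if (n_samples == 0) stop("empty sample stream")
  spc <- gate$samples_per_cycle
  n_content <- gate$n_bins_on + gate$n_bins_off
  n_cycles <- floor(n_samples / spc)
  if (n_cycles < 1) stop("sample stream shorter than one full cycle")
  if (n_samples - n_cycles * spc >= 1) {
    warning(sprintf("dropping trailing partial cycle (%d leftover samples)",
                    floor(n_samples - n_cycles * spc)))
  }
  starts <- floor((seq_len(n_cycles) - 1) * spc)  # 0-based
  idx <- outer(starts, seq_len(n_content), `+`)   # n_cycles x 312
  m <- raw_samples[idx]
  dim(m) <- dim(idx)
  on <- rowSums(m[, seq_len(gate$n_bins_on), drop = FALSE])
  off <- m[, gate$n_bins_on + seq_len(gate$n_bins_off), drop = FALSE]
  photon_trace(
    cycle_start_ms = (seq_len(n_cycles) - 1) * gate$cycle_period_us / 1000,
    on_phase_intensity = on,
    off_counts = off,
    gate = gate
  )
}

#' Flatten a photon trace back to a sample stream
#'
#' Inverse of [segment_cycles()] (up to the arbitrary placement of on-phase
#' counts, which are written into the first on-phase bin of each cycle).
#' Mainly useful for exercising the segmentation path on simulator output.
#'
#' @param trace A [photon_trace()].
#' @return Numeric vector of per-sample counts.
#' @export
trace_to_stream <- function(trace) {
  gate <- trace$gate
  spc <- gate$samples_per_cycle
  n_content <- gate$n_bins_on + gate$n_bins_off
  n_total <- ceiling(trace$n_cycles * spc)
  out <- numeric(n_total)
  starts <- floor((seq_len(trace$n_cycles) - 1) * spc)
  out[starts + 1] <- trace$on_phase_intensity
  idx <- outer(starts, gate$n_bins_on + seq_len(gate$n_bins_off), `+`)
  out[idx] <- trace$off_counts
  out
}
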