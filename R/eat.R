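#' EAT pooling windows
#'
#' Windows used to pool decays relative to detected RBC passages: decays
#' recorded 1-3.5 ms from an RBC edge (either side, on the plasma side) form
#' the "RBC border" pool, and decays at mid-distance between RBCs, over a
#' window of at least 5 ms, form the "inter-RBC" pool.
#'
#' @param border_min_ms,border_max_ms Border-pool offsets from an RBC edge.
#' @param inter_min_window_ms Minimum mid-gap window length for the
#'   inter-RBC pool.
#' @return Object of class `eat_windows`.
#' @export
eat_windows <- function(border_min_ms = 1.0, border_max_ms = 3.5,
                        inter_min_window_ms = 5.0) {
  stopifnot(border_min_ms < border_max_ms, inter_min_window_ms > 0,
            border_min_ms >= 0)
  structure(list(border_min_ms = border_min_ms,
                 border_max_ms = border_max_ms,
                 inter_min_window_ms = inter_min_window_ms),
            class = "eat_windows")
}

#' Detect RBC passages from on-phase fluorescence
#'
#' RBCs exclude the plasma dye, so each passage darkens the on-phase
#' fluorescence. Detection: lightly median-smoothed intensity is compared
#' against `baseline - f * (baseline - trough_floor)` where the baseline is
#' a rolling median and the trough floor a low quantile of the smoothed
#' signal; runs of at least `min_duration_cycles` below threshold become
#' events. A signal without dynamic range (no dips beyond noise) yields an
#' empty event list with a warning.
#'
#' @param on_intensity Per-cycle on-phase counts.
#' @param cycle_times_ms Cycle start times, ms.
#' @param f Threshold fraction between baseline and trough floor.
#' @param baseline_window Rolling-median window (cycles, odd).
#' @param smooth Pre-smoothing median window (cycles, odd).
#' @param min_duration_cycles Minimum event duration in cycles.
#' @param floor_quantile Quantile of the smoothed signal taken as the
#'   trough floor.
#' @return Data frame of class `rbc_events`: `entry_ms`, `exit_ms`,
#'   `trough_intensity`. Events are time-ordered and non-overlapping.
#' @export
detect_rbc_passages <- function(on_intensity, cycle_times_ms, f = 0.5,
                                baseline_window = 501, smooth = 3,
                                min_duration_cycles = 2,
                                floor_quantile = 0.01) {
  n <- length(on_intensity)
  stopifnot(length(cycle_times_ms) == n)
  if (n < 100) stop("need at least 100 cycles for RBC detection")

  sm <- stats::runmed(on_intensity, k = min(smooth, n) %/% 2 * 2 + 1)
  bw <- min(baseline_window, n) %/% 2 * 2 + 1
  baseline <- stats::runmed(sm, k = bw, endrule = "constant")
  trough_floor <- stats::quantile(sm, floor_quantile, names = FALSE)
  dyn_range <- stats::median(baseline) - trough_floor
  noise <- stats::mad(sm - baseline)
  if (dyn_range <= max(4 * noise, 1e-9)) {
    warning("no dynamic range in on-phase intensity: no RBC events detected")
    return(structure(data.frame(entry_ms = numeric(0), exit_ms = numeric(0),
                                trough_intensity = numeric(0)),
                     class = c("rbc_events", "data.frame")))
  }
  threshold <- baseline - f * (baseline - trough_floor)
  below <- sm < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_duration_cycles
  cycle_ms <- if (n > 1) stats::median(diff(cycle_times_ms)) else 0.25
  ev <- data.frame(
    entry_ms = cycle_times_ms[starts[keep]],
    exit_ms = cycle_times_ms[ends[keep]] + cycle_ms,
    trough_intensity = vapply(which(keep), function(i) {
      min(sm[starts[i]:ends[i]])
    }, numeric(1))
  )
  structure(ev, class = c("rbc_events", "data.frame"))
}

#' Classify acquisition cycles relative to RBC passages
#'
#' Partitions the cycles of a trace into `inside_rbc` (within an event),
#' `border` (distance to the nearest event edge, on the plasma side, within
#' the border window), `inter_rbc` (within the centered mid-gap window of
#' gaps long enough to hold both flanking border zones plus the minimum
#' inter window, i.e. gap >= 2 * border_max + inter_min), and
#' `unclassified` (everything else). Labels are exclusive, with precedence
#' inside > border > inter.
#'
#' @param events An `rbc_events` data frame (time-ordered).
#' @param trace A [photon_trace()].
#' @param windows An [eat_windows()].
#' @return Object of class `eat_classification`: `labels` (factor, one per
#'   cycle), `windows`, `events`, `trace`.
#' @export
classify_cycles <- function(events, trace, windows = eat_windows()) {
  t <- trace$cycle_start_ms
  n <- length(t)
  labels <- rep("unclassified", n)
  n_ev <- nrow(events)
  if (n_ev > 0) {
    if (is.unsorted(events$entry_ms)) stop("events must be time-ordered")
    i <- findInterval(t, events$entry_ms)
    inside <- i >= 1 & t <= events$exit_ms[pmax(i, 1)]
    d_prev <- ifelse(i >= 1, t - events$exit_ms[pmax(i, 1)], Inf)
    d_next <- ifelse(i < n_ev, events$entry_ms[pmin(i + 1, n_ev)] - t, Inf)
    d_edge <- pmin(pmax(d_prev, 0), pmax(d_next, 0))
    border <- !inside & d_edge >= windows$border_min_ms &
      d_edge <= windows$border_max_ms

    inter <- rep(FALSE, n)
    if (n_ev >= 2) {
      gap_lo <- events$exit_ms[-n_ev]
      gap_hi <- events$entry_ms[-1]
      gap <- gap_hi - gap_lo
      ok <- gap >= 2 * windows$border_max_ms + windows$inter_min_window_ms
      if (any(ok)) {
        mid <- (gap_lo + gap_hi) / 2
        half <- (gap - 2 * windows$border_max_ms) / 2
        for (g in which(ok)) {
          inter <- inter | (t >= mid[g] - half[g] & t <= mid[g] + half[g])
        }
      }
    }
    labels[inter & !border & !inside] <- "inter_rbc"
    labels[border] <- "border"
    labels[inside] <- "inside_rbc"
  }
  structure(list(
    labels = factor(labels, levels = c("inside_rbc", "border", "inter_rbc",
                                       "unclassified")),
    windows = windows,
    events = events,
    trace = trace
  ), class = "eat_classification")
}

#' @export
print.eat_classification <- function(x, ...) {
  cat("<eat_classification>\n")
  print(table(x$labels))
  invisible(x)
}

#' Pooled Po2 of one cycle class (fit-then-convert)
#'
#' Accumulates every cycle carrying the requested label into one decay,
#' fits a single lifetime and converts it once through the
#' temperature-matched calibration curve — the same fit-then-convert
#' contract as [po2_mean_from_trace()]. `label = "all"` pools every cycle.
#'
#' @param classification An [classify_cycles()] result.
#' @param label One of `"all"`, `"inside_rbc"`, `"border"`, `"inter_rbc"`,
#'   `"unclassified"`.
#' @param set A [calibration_set()] (or single curve).
#' @param temperature_c Sensor temperature, Celsius.
#' @param pool_floor Minimum number of cycles in the pool; lifetime fits on
#'   photon-starved pools are unstable.
#' @param conf Passed to [fit_lifetime()].
#' @return List: `po2_mmHg`, `fit` (`lifetime_fit`), `n_cycles`.
#' @export
po2_pool <- function(classification, label, set, temperature_c,
                     pool_floor = 500, conf = TRUE) {
  stopifnot(inherits(classification, "eat_classification"))
  idx <- if (identical(label, "all")) {
    seq_len(classification$trace$n_cycles)
  } else {
    which(classification$labels == label)
  }
  if (length(idx) < pool_floor) {
    stop(sprintf("pool '%s' holds %d cycles, below the floor of %d",
                 label, length(idx), pool_floor))
  }
  fit <- fit_lifetime(accumulate_decay(classification$trace, idx), conf = conf)
  list(po2_mmHg = po2_from_tau(set, fit$tau_us, temperature_c),
       fit = fit, n_cycles = length(idx))
}

#' RBC flux from detected events
#'
#' @param events An `rbc_events` data frame.
#' @param duration_s Observation duration, seconds (> 0).
#' @return Flux in RBC/s.
#' @export
rbc_flux <- function(events, duration_s) {
  if (duration_s <= 0) stop("duration_s must be positive")
  nrow(events) / duration_s
}

#' Po2 profile around the RBC edge (EAT profile)
#'
#' Bins cycles by signed time to the nearest RBC edge (negative inside the
#' RBC, positive in plasma) and computes a pooled fit-then-convert Po2 per
#' bin, tracing the shape of the erythrocyte-associated transient. Bins
#' holding fewer than `pool_floor` cycles are omitted.
#'
#' @param events An `rbc_events` data frame (>= 10 events).
#' @param trace A [photon_trace()].
#' @param set A [calibration_set()] (or single curve).
#' @param temperature_c Sensor temperature, Celsius.
#' @param bin_ms Offset bin width, ms.
#' @param max_offset_ms Largest plasma-side offset profiled.
#' @param pool_floor Minimum cycles per bin.
#' @return Data frame: `offset_ms` (bin center), `po2_mmHg`, `n_cycles`.
#' @export
eat_profile <- function(events, trace, set, temperature_c, bin_ms = 1.0,
                        max_offset_ms = 10, pool_floor = 500) {
  if (nrow(events) < 10) stop("need at least 10 events for an EAT profile")
  t <- trace$cycle_start_ms
  n_ev <- nrow(events)
  i <- findInterval(t, events$entry_ms)
  inside <- i >= 1 & t <= events$exit_ms[pmax(i, 1)]
  d_prev <- ifelse(i >= 1, t - events$exit_ms[pmax(i, 1)], Inf)
  d_next <- ifelse(i < n_ev, events$entry_ms[pmin(i + 1, n_ev)] - t, Inf)
  d_edge <- pmin(pmax(d_prev, 0), pmax(d_next, 0))
  # signed offset: negative inside the RBC (distance to the nearest edge)
  d_in <- pmin(t - events$entry_ms[pmax(i, 1)],
               events$exit_ms[pmax(i, 1)] - t)
  offset <- ifelse(inside, -pmax(d_in, 0), d_edge)

  breaks <- seq(-ceiling(max(events$exit_ms - events$entry_ms) / 2 + bin_ms),
                max_offset_ms, by = bin_ms)
  bin <- cut(offset, breaks, include.lowest = TRUE)
  out <- lapply(levels(bin), function(lv) {
    idx <- which(bin == lv & is.finite(offset))
    if (length(idx) < pool_floor) return(NULL)
    fit <- fit_lifetime(accumulate_decay(trace, idx), conf = FALSE)
    data.frame(
      offset_ms = mean(breaks[match(lv, levels(bin)) + 0:1]),
      po2_mmHg = po2_from_tau(set, fit$tau_us, temperature_c),
      n_cycles = length(idx))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
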