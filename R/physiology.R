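#' Hill-equation parameters for mouse hemoglobin
#'
#' Defaults are the C57BL/6 mouse values used for estimating cerebral
#' hemoglobin saturation from Po2: Hill coefficient 2.59 and P50 40.2 mmHg.
#'
#' @param n Hill coefficient (dimensionless, > 0).
#' @param p50_mmHg Half-saturation Po2, mmHg (> 0).
#' @return Object of class `hill_parameters`.
#' @export
hill_parameters <- function(n = 2.59, p50_mmHg = 40.2) {
  stopifnot(n > 0, p50_mmHg > 0)
  structure(list(n = n, p50_mmHg = p50_mmHg), class = "hill_parameters")
}

#' Hemoglobin saturation from Po2 (Hill equation)
#'
#' `SO2 = Po2^n / (Po2^n + P50^n)`; strictly increasing, 0 at Po2 = 0 and
#' exactly 0.5 at Po2 = P50.
#'
#' @param po2_mmHg Oxygen partial pressure(s), mmHg (non-negative).
#' @param hill A [hill_parameters()].
#' @return Saturation fraction(s) in [0, 1).
#' @export
so2_from_po2 <- function(po2_mmHg, hill = hill_parameters()) {
  if (any(po2_mmHg < 0)) stop("po2 must be non-negative")
  r <- (po2_mmHg / hill$p50_mmHg)^hill$n
  r / (1 + r)
}

#' Po2 from hemoglobin saturation (inverse Hill equation)
#'
#' `Po2 = P50 * (SO2 / (1 - SO2))^(1/n)`, the exact inverse of
#' [so2_from_po2()].
#'
#' @param so2 Saturation fraction(s), strictly inside (0, 1).
#' @param hill A [hill_parameters()].
#' @return Po2 in mmHg.
#' @export
po2_from_so2 <- function(so2, hill = hill_parameters()) {
  if (any(so2 <= 0 | so2 >= 1)) stop("so2 must lie strictly inside (0, 1)")
  hill$p50_mmHg * (so2 / (1 - so2))^(1 / hill$n)
}

#' Percent change relative to a baseline
#'
#' @param baseline Baseline value(s), non-zero.
#' @param value New value(s).
#' @return `100 * (value - baseline) / baseline`.
#' @export
percent_change <- function(baseline, value) {
  if (any(baseline == 0)) stop("baseline must be non-zero")
  100 * (value - baseline) / baseline
}

#' One capillary-condition measurement record
#'
#' @param capillary_id Identifier pairing conditions of the same capillary.
#' @param condition_label Condition name (e.g. `"awake_dry_37C"`).
#' @param po2_mean_mmHg,po2_rbc_mmHg,po2_inter_rbc_mmHg Pooled Po2 values.
#' @param so2_fraction Hemoglobin saturation (from Po2 RBC), in [0, 1].
#' @param rbc_flux_per_s RBC flux.
#' @param velocity_mm_s RBC velocity (optional, `NA` if not measured).
#' @param temperature_c Sensor temperature used for conversion.
#' @param capillary_diameter_um Metadata; small cortical capillaries run
#'   around 3.1 +/- 0.5 um.
#' @return One-row data frame of class `capillary_result`.
#' @export
capillary_result <- function(capillary_id, condition_label,
                             po2_mean_mmHg, po2_rbc_mmHg, po2_inter_rbc_mmHg,
                             so2_fraction, rbc_flux_per_s,
                             velocity_mm_s = NA_real_,
                             temperature_c = NA_real_,
                             capillary_diameter_um = NA_real_) {
  stopifnot(po2_mean_mmHg >= 0, po2_rbc_mmHg >= 0, po2_inter_rbc_mmHg >= 0,
            so2_fraction >= 0, so2_fraction <= 1, rbc_flux_per_s >= 0)
  structure(data.frame(
    capillary_id = as.character(capillary_id),
    condition_label = as.character(condition_label),
    po2_mean_mmHg = po2_mean_mmHg,
    po2_rbc_mmHg = po2_rbc_mmHg,
    po2_inter_rbc_mmHg = po2_inter_rbc_mmHg,
    so2_fraction = so2_fraction,
    rbc_flux_per_s = rbc_flux_per_s,
    velocity_mm_s = velocity_mm_s,
    temperature_c = temperature_c,
    capillary_diameter_um = capillary_diameter_um,
    stringsAsFactors = FALSE
  ), class = c("capillary_result", "data.frame"))
}

#' Paired comparison of capillary measurements across conditions
#'
#' Pairs measurements of the same capillary under different conditions and
#' summarizes, per metric: per-capillary deltas and percent changes against
#' the baseline condition, and group mean +/- s.e.m. per condition. The
#' capillary is the statistical unit; capillaries missing a condition are
#' excluded from that pairing (with a note in `excluded`).
#'
#' @param results Data frame of stacked [capillary_result()] rows.
#' @param baseline Baseline condition label.
#' @param metrics Metric columns to compare.
#' @return Object of class `condition_comparison`: `summary` (condition x
#'   metric mean, sem, n), `changes` (per capillary x condition x metric
#'   delta and percent change vs baseline), `excluded` (capillary/condition
#'   pairs dropped), `baseline`.
#' @export
compare_conditions <- function(results, baseline,
                               metrics = c("po2_mean_mmHg", "po2_rbc_mmHg",
                                           "po2_inter_rbc_mmHg",
                                           "so2_fraction", "rbc_flux_per_s",
                                           "velocity_mm_s")) {
  stopifnot(is.data.frame(results),
            all(c("capillary_id", "condition_label") %in% names(results)))
  metrics <- intersect(metrics, names(results))
  if (!baseline %in% results$condition_label) {
    stop(sprintf("baseline condition '%s' not present", baseline))
  }
  # canonical order -> permutation invariance of the input
  results <- results[order(results$capillary_id, results$condition_label), ]
  conds <- sort(unique(results$condition_label))
  ids <- sort(unique(results$capillary_id))
  per_cap <- table(results$capillary_id)
  if (any(per_cap < 2)) {
    stop("every capillary needs measurements under at least 2 conditions")
  }

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary_df <- do.call(rbind, lapply(conds, function(cn) {
    sub <- results[results$condition_label == cn, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(m) {
      v <- sub[[m]][is.finite(sub[[m]])]
      data.frame(condition_label = cn, metric = m,
                 mean = mean(v), sem = sem(v), n_capillaries = length(v))
    }))
  }))

  base <- results[results$condition_label == baseline, , drop = FALSE]
  changes <- list(); excluded <- list()
  for (cn in setdiff(conds, baseline)) {
    other <- results[results$condition_label == cn, , drop = FALSE]
    common <- intersect(base$capillary_id, other$capillary_id)
    missing <- setdiff(union(base$capillary_id, other$capillary_id), common)
    if (length(missing)) {
      excluded[[cn]] <- data.frame(condition_label = cn,
                                   capillary_id = missing)
      message(sprintf("compare_conditions: %d capillar%s lack a %s/%s pair",
                      length(missing),
                      if (length(missing) == 1) "y" else "ies",
                      baseline, cn))
    }
    for (id in common) {
      b <- base[base$capillary_id == id, , drop = FALSE][1, ]
      o <- other[other$capillary_id == id, , drop = FALSE][1, ]
      for (m in metrics) {
        if (!is.finite(b[[m]]) || !is.finite(o[[m]])) next
        changes[[length(changes) + 1]] <- data.frame(
          capillary_id = id, condition_label = cn, metric = m,
          baseline_value = b[[m]], value = o[[m]],
          delta = o[[m]] - b[[m]],
          percent_change = if (b[[m]] != 0) {
            percent_change(b[[m]], o[[m]])
          } else NA_real_)
      }
    }
  }
  if (length(changes) == 0) stop("no complete capillary pairs to compare")
  structure(list(
    summary = summary_df,
    changes = do.call(rbind, changes),
    excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
    baseline = baseline
  ), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> baseline: %s\n", x$baseline))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
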