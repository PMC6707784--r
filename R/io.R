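#' Read a calibration CSV
#'
#' Expected header columns: `lifetime_us`, `po2_mmHg`, `temperature_c`. One
#' file may hold runs at several temperatures.
#'
#' @param path CSV path.
#' @return Data frame of calibration points.
#' @export
read_calibration_csv <- function(path) {
  pts <- utils::read.csv(path)
  need <- c("lifetime_us", "po2_mmHg", "temperature_c")
  if (!all(need %in% names(pts))) {
    stop(sprintf("calibration CSV must carry columns: %s",
                 paste(need, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(pts[need]) |
                 pts$lifetime_us <= 0)
  if (length(bad)) {
    stop(sprintf("malformed calibration row(s) at line(s): %s",
                 paste(bad + 1, collapse = ", ")))
  }
  pts
}

#' Write calibration points to CSV
#' @param points Data frame with `lifetime_us`, `po2_mmHg`, `temperature_c`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Fit calibration curves for every temperature in a CSV
#'
#' @param path Calibration CSV (see [read_calibration_csv()]).
#' @return A [calibration_set()] with one fitted curve per distinct
#'   temperature in the file.
#' @export
fit_calibration_csv <- function(path) {
  pts <- read_calibration_csv(path)
  if (nrow(pts) == 0) stop("empty calibration file")
  temps <- sort(unique(pts$temperature_c))
  curves <- lapply(temps, function(tc) {
    fit_calibration_curve(pts[pts$temperature_c == tc, , drop = FALSE], tc)
  })
  calibration_set(curves)
}

#' Write a calibration set to JSON
#'
#' One record per temperature: `temperature_c`, `tau0_us`,
#' `kq_per_us_mmHg`, `fit_residual`, `valid_po2_range`.
#'
#' @param set A [calibration_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(set, path) {
  doc <- list(
    interpolation_policy = set$interpolation_policy,
    curves = lapply(set$curves, function(cv) {
      list(temperature_c = cv$temperature_c,
           tau0_us = cv$tau0_us,
           kq_per_us_mmHg = cv$kq_per_us_mmHg,
           fit_residual = cv$fit_residual,
           valid_po2_range = cv$valid_po2_range,
           warnings = cv$warnings)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration set from JSON
#' @param path JSON written by [write_calibration_json()].
#' @return A [calibration_set()].
#' @export
read_calibration_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  curves <- lapply(doc$curves, function(cv) {
    structure(list(
      temperature_c = cv$temperature_c,
      tau0_us = cv$tau0_us,
      kq_per_us_mmHg = cv$kq_per_us_mmHg,
      fit_residual = cv$fit_residual,
      valid_po2_range = as.numeric(cv$valid_po2_range),
      warnings = as.character(cv$warnings %||% character(0))
    ), class = "calibration_curve")
  })
  calibration_set(curves, doc$interpolation_policy %||% "linear")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gated acquisition to the CSV container
#'
#' One row per cycle: `start_ms`, `on_intensity`, then one `off_b###` column
#' per off-phase bin. The gate configuration (and any extra metadata) goes
#' into a JSON sidecar at `<path>.json`.
#'
#' @param trace A [photon_trace()].
#' @param path Output CSV path.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, meta = list()) {
  df <- data.table::as.data.table(trace$off_counts)
  data.table::setnames(df, sprintf("off_b%03d", seq_len(ncol(df))))
  df <- cbind(data.table::data.table(start_ms = trace$cycle_start_ms,
                                     on_intensity = trace$on_phase_intensity),
              df)
  data.table::fwrite(df, path)
  g <- trace$gate
  sidecar <- c(list(gate = list(
    cycle_period_us = g$cycle_period_us,
    excitation_on_us = g$excitation_on_us,
    collection_off_us = g$collection_off_us,
    discard_after_gate_us = g$discard_after_gate_us,
    sampling_rate_hz = g$sampling_rate_hz
  )), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gated acquisition from the CSV container
#' @param path CSV written by [write_trace_csv()] (sidecar `<path>.json`
#'   must exist).
#' @return A [photon_trace()].
#' @export
read_trace_csv <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("missing gate sidecar '%s'", sidecar_path))
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  gate <- gate_config(
    cycle_period_us = sc$gate$cycle_period_us,
    excitation_on_us = sc$gate$excitation_on_us,
    collection_off_us = sc$gate$collection_off_us,
    discard_after_gate_us = sc$gate$discard_after_gate_us,
    sampling_rate_hz = sc$gate$sampling_rate_hz
  )
  df <- data.table::fread(path)
  off_cols <- grep("^off_b", names(df), value = TRUE)
  photon_trace(df$start_ms, df$on_intensity,
               as.matrix(df[, off_cols, with = FALSE]), gate)
}

#' Write a line-scan image as TIFF plus JSON sidecar
#'
#' The image is stored as a single-channel TIFF (counts scaled to 16-bit);
#' `line_period_ms`, `pixel_size_um` and the scale factor go into
#' `<path>.json`.
#'
#' @param image A `line_scan_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_linescan_tiff <- function(image, path) {
  stopifnot(inherits(image, "line_scan_image"))
  scale <- max(image$pixels, 1)
  tiff::writeTIFF(image$pixels / scale, path, bits.per.sample = 16)
  jsonlite::write_json(list(line_period_ms = image$line_period_ms,
                            pixel_size_um = image$pixel_size_um,
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a line-scan TIFF written by [write_linescan_tiff()]
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return A `line_scan_image`.
#' @export
read_linescan_tiff <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("missing line-scan sidecar '%s'", sidecar_path))
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * sc$intensity_scale
  line_scan_image(px, sc$line_period_ms, sc$pixel_size_um)
}

#' Write stacked capillary results as CSV and JSON
#'
#' @param results Data frame of [capillary_result()] rows.
#' @param path_csv,path_json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_capillary_results <- function(results, path_csv = NULL,
                                    path_json = NULL) {
  if (!is.null(path_csv)) utils::write.csv(results, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(results, path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(c(path_csv, path_json))
}

#' Export detected RBC events as CSV
#' @param events An `rbc_events` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events)[c("entry_ms", "exit_ms")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write the planted ground truth of a simulation as JSON
#' @param truth A [synthetic_truth()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
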