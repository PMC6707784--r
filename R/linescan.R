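#' Line-scan image container
#'
#' @param pixels Matrix of intensities; rows are successive line scans
#'   (time), columns are positions along the capillary.
#' @param line_period_ms Time per line, ms.
#' @param pixel_size_um Pixel size along the line, micrometers.
#' @return Object of class `line_scan_image`.
#' @export
line_scan_image <- function(pixels, line_period_ms, pixel_size_um) {
  pixels <- as.matrix(pixels)
  stopifnot(line_period_ms > 0, pixel_size_um > 0)
  structure(list(
    pixels = pixels,
    line_period_ms = line_period_ms,
    pixel_size_um = pixel_size_um,
    duration_s = nrow(pixels) * line_period_ms / 1000
  ), class = "line_scan_image")
}

#' @export
print.line_scan_image <- function(x, ...) {
  cat(sprintf("<line_scan_image> %d lines x %d px, %.2f ms/line, %.2f um/px (%.1f s)\n",
              nrow(x$pixels), ncol(x$pixels), x$line_period_ms,
              x$pixel_size_um, x$duration_s))
  invisible(x)
}

# Radon-style angle objective: project all pixels of each block onto the
# axis perpendicular to candidate streaks at angle theta (from the time
# axis) and measure the count-weighted variance of the projection-bin
# means. The variance peaks when the projection runs along the streaks.
.angle_objective <- function(blocks, b_rows, n_cols, theta_deg) {
  th <- theta_deg * pi / 180
  tt <- rep(seq_len(b_rows) - 1, times = n_cols)
  xx <- rep(seq_len(n_cols) - 1, each = b_rows)
  s <- xx * cos(th) - tt * sin(th)
  bin <- floor(s - min(s)) + 1L
  sums <- rowsum(blocks, bin, reorder = TRUE)
  cnt <- tabulate(bin)
  cnt <- cnt[cnt > 0]
  keep <- cnt >= max(3, 0.5 * stats::median(cnt))
  means <- sums[keep, , drop = FALSE] / cnt[keep]
  w <- cnt[keep] / sum(cnt[keep])
  # count-weighted variance of bin means, averaged over blocks
  mbar <- colSums(means * w)
  mean(colSums(w * (means - rep(mbar, each = nrow(means)))^2))
}

#' Estimate RBC velocity from a line-scan image
#'
#' Radon-transform streak-angle estimation: the image (column means
#' removed, globally normalized, tiled into blocks) is projected at a sweep
#' of candidate angles and the angle maximizing the variance of the
#' projection identifies the streak direction. The sweep is coarse-to-fine
#' down to `angle_step_deg` (0.25 degrees) and refined by parabolic
#' interpolation of the objective around its peak. Velocity follows from
#' the streak slope: `v = tan(theta) * pixel_size_um / line_period_ms`
#' (mm/s), where `theta` is measured from the time axis, so 45-degree
#' streaks at unit scaling give exactly 1 mm/s. Sign encodes flow
#' direction.
#'
#' @param image A `line_scan_image` (at least 64 x 32, non-constant).
#' @param angle_step_deg Final sweep resolution, degrees.
#' @param max_angle_deg Largest |angle| swept (caps measurable speed).
#' @param block_rows Rows per analysis block (default `4 * ncol`, capped at
#'   the image height).
#' @return Object of class `velocity_estimate`: `velocity_mm_s`,
#'   `angle_deg`, `confidence` (normalized peak sharpness in [0, 1]),
#'   `low_velocity` (flag: streaks indistinguishable from vertical;
#'   velocity reported as 0), `window_start_s`, `window_end_s`.
#' @export
estimate_velocity <- function(image, angle_step_deg = 0.25,
                              max_angle_deg = 85, block_rows = NULL) {
  stopifnot(inherits(image, "line_scan_image"))
  px <- image$pixels
  if (nrow(px) < 64 || ncol(px) < 32) {
    stop("line-scan image must be at least 64 x 32 pixels")
  }
  if (stats::sd(px) == 0) stop("constant line-scan image: no streaks to fit")

  # Static (time-invariant) structure is vertical: RBCs moving below the
  # resolvable floor leave column-aligned streaks that would otherwise be
  # destroyed by the per-column mean removal below. If column means carry
  # most of the image variance, report zero velocity with the flag set.
  px0 <- px - mean(px)
  static_ratio <- nrow(px0) * sum(colMeans(px0)^2) /
    max(sum(px0^2), .Machine$double.eps)
  if (static_ratio > 0.5) {
    return(structure(list(
      velocity_mm_s = 0, angle_deg = 0,
      confidence = min(max(static_ratio, 0), 1), low_velocity = TRUE,
      window_start_s = 0, window_end_s = image$duration_s
    ), class = "velocity_estimate"))
  }

  # preprocessing: remove static (per-column) structure, normalize globally
  px <- sweep(px, 2, colMeans(px))
  px <- px / max(stats::sd(px), .Machine$double.eps)

  n_cols <- ncol(px)
  if (is.null(block_rows)) block_rows <- min(nrow(px), 4 * n_cols)
  n_blocks <- nrow(px) %/% block_rows
  # stack blocks as columns: (block_rows * n_cols) x n_blocks, column-major
  # within a block (time fastest), matching .angle_objective's coordinates
  blocks <- vapply(seq_len(n_blocks), function(b) {
    as.vector(px[(b - 1) * block_rows + seq_len(block_rows), ])
  }, numeric(block_rows * n_cols))
  if (n_blocks == 1) blocks <- matrix(blocks, ncol = 1)

  obj <- function(th) .angle_objective(blocks, block_rows, n_cols, th)
  coarse <- seq(-max_angle_deg, max_angle_deg, by = 1)
  v_coarse <- vapply(coarse, obj, numeric(1))
  best <- coarse[which.max(v_coarse)]

  fine <- seq(max(-max_angle_deg, best - 1.5),
              min(max_angle_deg, best + 1.5), by = angle_step_deg)
  v_fine <- vapply(fine, obj, numeric(1))
  k <- which.max(v_fine)
  theta <- fine[k]
  if (k > 1 && k < length(v_fine)) {   # parabolic peak refinement
    denom <- v_fine[k - 1] - 2 * v_fine[k] + v_fine[k + 1]
    if (denom < 0) {
      theta <- theta + angle_step_deg / 2 * (v_fine[k - 1] - v_fine[k + 1]) / denom
    }
  }

  conf <- (max(v_coarse) - stats::median(v_coarse)) /
    max(max(v_coarse) - min(v_coarse), .Machine$double.eps)
  conf <- min(max(conf, 0), 1)

  low <- abs(theta) < angle_step_deg
  velocity <- if (low) 0 else {
    tan(theta * pi / 180) * image$pixel_size_um / image$line_period_ms
  }
  structure(list(
    velocity_mm_s = velocity,
    angle_deg = theta,
    confidence = conf,
    low_velocity = low,
    window_start_s = 0,
    window_end_s = image$duration_s
  ), class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("<velocity_estimate> %.3f mm/s (angle %.2f deg, confidence %.2f)%s\n",
              x$velocity_mm_s, x$angle_deg, x$confidence,
              if (x$low_velocity) " [below resolvable floor]" else ""))
  invisible(x)
}

#' Sliding-window velocity estimates
#'
#' @param image A `line_scan_image`.
#' @param window_s Window length, seconds (<= record duration).
#' @param step_s Window step (default: non-overlapping).
#' @param ... Passed to [estimate_velocity()].
#' @return Data frame with one row per window: `window_start_s`,
#'   `window_end_s`, `velocity_mm_s`, `angle_deg`, `confidence`,
#'   `low_velocity`.
#' @export
windowed_velocity <- function(image, window_s, step_s = window_s, ...) {
  stopifnot(inherits(image, "line_scan_image"))
  if (window_s > image$duration_s) {
    stop("window_s exceeds the record duration")
  }
  rows_per_win <- floor(window_s * 1000 / image$line_period_ms)
  rows_step <- max(1, floor(step_s * 1000 / image$line_period_ms))
  starts <- seq(1, nrow(image$pixels) - rows_per_win + 1, by = rows_step)
  out <- lapply(starts, function(s) {
    sub <- line_scan_image(image$pixels[s + seq_len(rows_per_win) - 1, ],
                           image$line_period_ms, image$pixel_size_um)
    est <- estimate_velocity(sub, ...)
    data.frame(
      window_start_s = (s - 1) * image$line_period_ms / 1000,
      window_end_s = (s - 1 + rows_per_win) * image$line_period_ms / 1000,
      velocity_mm_s = est$velocity_mm_s,
      angle_deg = est$angle_deg,
      confidence = est$confidence,
      low_velocity = est$low_velocity)
  })
  do.call(rbind, out)
}
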