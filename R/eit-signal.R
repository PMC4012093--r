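#' Extract regional impedance curves from a tomogram series
#'
#' Sums the pixel values of each frame over the rows of every region of
#' interest, producing the four regional impedance time series
#' `Z_global(t)`, `Z_ventral(t)`, `Z_middle(t)` and `Z_dorsal(t)`. The
#' global ROI is the union of the three sub-ROIs, so
#' `Z_global = Z_ventral + Z_middle + Z_dorsal` holds at every sample (up to
#' floating-point association). Excluded rows contribute to no ROI.
#'
#' @param frames a [pixel_frame_series()].
#' @param layout a [roi_layout()]; its matrix dimensions must match the
#'   frames.
#' @return An object of class `regional_impedance_series` holding a
#'   `T x 4` matrix of ROI sums plus `fs` and `t0`.
#' @export
extract_roi_series <- function(frames, layout = roi_layout()) {
  stopifnot(inherits(frames, "pixel_frame_series"),
            inherits(layout, "roi_layout"))
  d <- dim(frames$frames)
  if (d[2] != layout$n_rows || d[3] != layout$n_cols) {
    stop(sprintf("frame matrix is %dx%d but layout expects %dx%d",
                 d[2], d[3], layout$n_rows, layout$n_cols), call. = FALSE)
  }
  # flatten to T x (rows*cols); element (t, r, c) sits in column
  # (c-1)*n_rows + r because R arrays are column-major
  flat <- matrix(frames$frames, nrow = d[1])
  z <- matrix(0, nrow = d[1], ncol = 4L,
              dimnames = list(NULL, roi_names()))
  for (roi in roi_names()) {
    rows <- roi_row_indices(layout, roi)
    cols <- as.vector(outer(rows, (seq_len(d[3]) - 1L) * d[2], "+"))
    z[, roi] <- rowSums(flat[, cols, drop = FALSE])
  }
  new_regional_series(z, frames$fs, frames$t0, "regional_impedance_series")
}

#' Tidal impedance amplitude of the global signal
#'
#' Computes the tidal difference `Z_T` (amplitude between inspiration and
#' expiration) of the global relative impedance signal: within every
#' complete respiratory cycle the peak-to-trough amplitude of
#' `Z_global(t)` is taken, and `Z_T` is the mean amplitude across complete
#' breaths. `Z_T` calibrates impedance to volume via [calibrate_volume()].
#'
#' The per-breath amplitude is max minus min within the cycle window rather
#' than the difference of the boundary samples, which makes the estimate
#' immune to one-sample jitter of the detected cycle boundaries.
#'
#' @param z a `regional_impedance_series` (or `regional_volume_series`).
#' @param seg a [breath_segmentation][segment_breaths()] on the same
#'   timebase.
#' @return The scalar tidal amplitude (dimensionless for impedance input).
#' @export
compute_tidal_amplitude <- function(z, seg) {
  stopifnot(inherits(seg, "breath_segmentation"))
  cyc <- seg$cycles[seg$cycles$complete, , drop = FALSE]
  if (nrow(cyc) == 0L) {
    stop("no complete breath in segmentation", call. = FALSE)
  }
  g <- z$series[, "global"]
  amp <- vapply(seq_len(nrow(cyc)), function(i) {
    w <- g[cyc$start[i]:cyc$end[i]]
    max(w) - min(w)
  }, numeric(1))
  z_t <- mean(amp)
  if (z_t <= 0) {
    stop("zero tidal amplitude: record cannot be calibrated", call. = FALSE)
  }
  z_t
}

#' Calibrate regional impedance to volume
#'
#' Converts every regional impedance curve to a volume curve in ml by
#' `V_ROI(t) = Z_ROI(t) * v_t / z_t`, where `v_t` is the tidal volume set
#' at the ventilator and `z_t` the tidal impedance amplitude from
#' [compute_tidal_amplitude()]. A single global `z_t` calibrates all four
#' ROIs, so the regional volumes represent the regional distribution of the
#' tidal volume and remain additive.
#'
#' @param z a `regional_impedance_series`.
#' @param v_t tidal volume in ml (> 0).
#' @param z_t tidal impedance amplitude (> 0).
#' @return An object of class `regional_volume_series`.
#' @export
calibrate_volume <- function(z, v_t, z_t) {
  stopifnot(inherits(z, "regional_impedance_series"))
  if (!is.numeric(v_t) || length(v_t) != 1L || !is.finite(v_t) || v_t <= 0) {
    stop("`v_t` must be a positive tidal volume in ml", call. = FALSE)
  }
  if (!is.numeric(z_t) || length(z_t) != 1L || !is.finite(z_t) || z_t <= 0) {
    stop("`z_t` must be a positive tidal impedance amplitude", call. = FALSE)
  }
  v <- z$series * (v_t / z_t)
  new_regional_series(v, z$fs, z$t0, "regional_volume_series",
                      extra = list(calibration = list(v_t = v_t, z_t = z_t)))
}

#' Regional gas flow as first derivative of the volume curves
#'
#' Differentiates every regional volume curve by the backward difference
#' `V'(t_n) = (V(t_n) - V(t_(n-1))) / (t_n - t_(n-1))`, defined at every
#' recorded time point except the first. The flow series therefore has one
#' sample less than the volume series and starts at `t0 + 1/fs`.
#'
#' No temporal filtering is applied before differentiation; robustness of
#' the late-flow metrics against the cardiac oscillation comes from the
#' windowed estimator in [late_flow()].
#'
#' @param v a `regional_volume_series`.
#' @return An object of class `regional_flow_series` in ml/s.
#' @export
differentiate <- function(v) {
  stopifnot(inherits(v, "regional_volume_series"))
  n <- nrow(v$series)
  if (n < 2L) stop("need at least 2 volume samples", call. = FALSE)
  f <- apply(v$series, 2L, diff) * v$fs
  if (!is.matrix(f)) f <- matrix(f, nrow = 1L, dimnames = list(NULL, roi_names()))
  new_regional_series(f, v$fs, v$t0 + 1 / v$fs, "regional_flow_series")
}
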