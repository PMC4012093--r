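#' Tomogram time series
#'
#' Container for a sequence of reconstructed EIT tomograms: `T` frames of an
#' `n_rows x n_cols` matrix of dimensionless relative impedance change,
#' sampled uniformly at `fs` frames per second.
#'
#' @param frames numeric array of dimension `c(T, n_rows, n_cols)`.
#' @param fs sampling rate in frames/s (the reference device records 13
#'   tomograms per second).
#' @param t0 start time in s.
#' @return An object of class `pixel_frame_series`.
#' @export
pixel_frame_series <- function(frames, fs, t0 = 0) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a T x rows x cols array", call. = FALSE)
  }
  if (dim(frames)[1] < 2L) stop("need at least 2 frames", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive number", call. = FALSE)
  }
  if (!all(is.finite(frames))) {
    stop("all pixel values must be finite", call. = FALSE)
  }
  structure(list(frames = frames, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "pixel_frame_series")
}

#' @export
print.pixel_frame_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<pixel_frame_series> %d frames of %dx%d pixels @ %g frames/s (%.1f s)\n",
              d[1], d[2], d[3], x$fs, d[1] / x$fs))
  invisible(x)
}

# shared constructor for the three per-ROI series classes; `series` is a
# T x 4 matrix with columns global, ventral, middle, dorsal
new_regional_series <- function(series, fs, t0, class, extra = list()) {
  stopifnot(is.matrix(series), identical(colnames(series), roi_names()))
  structure(c(list(series = series, fs = as.numeric(fs), t0 = as.numeric(t0)),
              extra),
            class = class)
}

#' @export
print.regional_impedance_series <- function(x, ...) {
  cat(sprintf("<regional_impedance_series> %d samples @ %g Hz, ROIs: %s\n",
              nrow(x$series), x$fs, paste(roi_names(), collapse = ", ")))
  invisible(x)
}

#' @export
print.regional_volume_series <- function(x, ...) {
  cat(sprintf("<regional_volume_series> %d samples @ %g Hz [ml], V_T = %g ml, Z_T = %g\n",
              nrow(x$series), x$fs, x$calibration$v_t, x$calibration$z_t))
  invisible(x)
}

#' @export
print.regional_flow_series <- function(x, ...) {
  cat(sprintf("<regional_flow_series> %d samples @ %g Hz [ml/s]\n",
              nrow(x$series), x$fs))
  invisible(x)
}

#' Sample times of a series
#'
#' @param x a series object with `fs` and `t0`.
#' @return numeric vector of sample times in s.
#' @export
series_times <- function(x) {
  n <- if (is.matrix(x$series)) nrow(x$series) else length(x$flow)
  x$t0 + (seq_len(n) - 1) / x$fs
}

#' Spirometric flow trace
#'
#' @param flow numeric vector of airway flow samples in ml/s (inspiration
#'   positive).
#' @param fs sampling rate in Hz (default 100, the reference spirometer).
#' @param t0 start time in s.
#' @return An object of class `spiro_flow_series`.
#' @export
spiro_flow_series <- function(flow, fs = 100, t0 = 0) {
  if (!is.numeric(flow) || length(flow) < 2L || !all(is.finite(flow))) {
    stop("`flow` must be a finite numeric vector of length >= 2", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive number", call. = FALSE)
  }
  structure(list(flow = as.numeric(flow), fs = as.numeric(fs),
                 t0 = as.numeric(t0)),
            class = "spiro_flow_series")
}

#' @export
print.spiro_flow_series <- function(x, ...) {
  cat(sprintf("<spiro_flow_series> %d samples @ %g Hz (%.1f s)\n",
              length(x$flow), x$fs, length(x$flow) / x$fs))
  invisible(x)
}
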