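#' Peak inspiratory and expiratory flow per breath and region
#'
#' The regional maximum of the flow curve within a respiratory cycle is the
#' peak inspiratory flow (PIF), the regional minimum the peak expiratory
#' flow (PEF, negative by sign convention). Peaks are searched over the
#' whole cycle, not restricted to the ventilator phase halves; ties are
#' broken by the earliest sample. Incomplete cycles are reported with `NA`
#' metrics.
#'
#' @param flow a `regional_flow_series` from [differentiate()].
#' @param seg the [breath_segmentation][segment_breaths()] of the same
#'   record.
#' @return data frame with one row per (breath, ROI): `pif`, `t_pif`,
#'   `pef`, `t_pef` (times on the flow timebase).
#' @export
detect_peak_flows <- function(flow, seg) {
  stopifnot(inherits(flow, "regional_flow_series"),
            inherits(seg, "breath_segmentation"))
  nf <- nrow(flow$series)
  out <- list()
  for (b in seq_len(nrow(seg$cycles))) {
    cyc <- seg$cycles[b, ]
    for (roi in roi_names()) {
      if (!cyc$complete) {
        out[[length(out) + 1L]] <- data.frame(
          breath = b, roi = roi, complete = FALSE,
          pif = NA_real_, t_pif = NA_real_, pef = NA_real_, t_pef = NA_real_)
        next
      }
      ks <- seq.int(cyc$start, min(cyc$end - 1L, nf))
      f <- flow$series[ks, roi]
      imax <- which.max(f)                 # earliest tie wins
      imin <- which.min(f)
      out[[length(out) + 1L]] <- data.frame(
        breath = b, roi = roi, complete = TRUE,
        pif = f[imax], t_pif = flow$t0 + (ks[imax] - 1) / flow$fs,
        pef = f[imin], t_pef = flow$t0 + (ks[imin] - 1) / flow$fs)
    }
  }
  do.call(rbind, out)
}

#' Late (mean) flow as the average slope of the volume curve
#'
#' Estimates the late inspiratory or expiratory flow as the average slope
#' of the volume curve over a window of `window` seconds starting `delay`
#' seconds after the respective flow peak. The windowed average rejects the
#' cardiac oscillation riding on the aeration signal.
#'
#' Two estimators are available: `"ols"` (default), the ordinary
#' least-squares slope of V against t over the samples in the window, and
#' `"endpoint"`, the difference quotient between the boundary samples. The
#' OLS slope is markedly more robust against a cardiac sinusoid that does
#' not complete an integer number of periods in the window.
#'
#' Window boundaries snap to the nearest sample. When less than 80% of the
#' nominal samples fall inside the record (or inside the breath, via
#' `clip`), the estimate is computed on the truncated window and flagged.
#'
#' @param v volume samples: a `regional_volume_series` or a numeric vector
#'   (then `fs` is required).
#' @param t_peak time of the flow peak in s.
#' @param delay,window window placement in s (defaults 0.5 and 3.0).
#' @param estimator `"ols"` or `"endpoint"`.
#' @param roi ROI column when `v` is a regional series.
#' @param fs,t0 sampling rate and start time for numeric input.
#' @param clip optional inclusive sample-index range of the breath,
#'   `c(first, last)`; the window is truncated to it.
#' @return list with `value` (ml/s), `n` samples used, `expected_n`, and
#'   logical `truncated`.
#' @export
late_flow <- function(v, t_peak, delay = 0.5, window = 3.0,
                      estimator = c("ols", "endpoint"), roi = "global",
                      fs = NULL, t0 = 0, clip = NULL) {
  estimator <- match.arg(estimator)
  if (inherits(v, "regional_volume_series") ||
      inherits(v, "regional_impedance_series")) {
    x <- v$series[, roi]
    fs <- v$fs
    t0 <- v$t0
  } else {
    x <- as.numeric(v)
    if (is.null(fs)) stop("`fs` is required for numeric input", call. = FALSE)
  }
  if (delay < 0 || window <= 0) {
    stop("`delay` must be >= 0 and `window` > 0", call. = FALSE)
  }
  n <- length(x)
  i0 <- snap_index(t_peak + delay, t0, fs)
  i1 <- snap_index(t_peak + delay + window, t0, fs)
  expected_n <- i1 - i0 + 1L
  lo <- max(1L, i0, if (!is.null(clip)) clip[1L] else 1L)
  hi <- min(n, i1, if (!is.null(clip)) clip[2L] else n)
  if (hi < lo + 1L) stop("empty late-flow window", call. = FALSE)
  idx <- seq.int(lo, hi)
  tt <- t0 + (idx - 1) / fs
  vv <- x[idx]
  value <- if (estimator == "ols") {
    ols_slope(tt, vv)
  } else {
    (vv[length(vv)] - vv[1L]) / (tt[length(tt)] - tt[1L])
  }
  list(value = value, n = length(idx), expected_n = expected_n,
       truncated = length(idx) < 0.8 * expected_n)
}

# nearest-sample index (1-based) for a target time; half-up rounding with a
# small relative tolerance so that targets landing exactly between samples
# (e.g. a 0.5 s delay = 6.5 frames at 13 Hz) resolve identically no matter
# how the target time was accumulated in floating point
snap_index <- function(t_target, t0, fs) {
  y <- (t_target - t0) * fs + 0.5
  as.integer(floor(y + 1e-10 * max(1, abs(y)))) + 1L
}

ols_slope <- function(t, v) {
  tc <- t - mean(t)
  sum(tc * (v - mean(v))) / sum(tc * tc)
}

#' Extract the four phase metrics per breath and region
#'
#' For every complete breath and every ROI: PIF and PEF from
#' [detect_peak_flows()], LIF as the [late_flow()] after the PIF time and
#' LEF as the late flow after the PEF time. Quality flags record window
#' truncation and flow reversal within a phase (a regional flow sample
#' opposing the phase of the regional volume curve, e.g. pendelluft);
#' flagged values are reported signed, never clipped.
#'
#' @param flow a `regional_flow_series`.
#' @param volume the matching `regional_volume_series`.
#' @param seg the record's [breath_segmentation][segment_breaths()].
#' @param delay,window,estimator passed to [late_flow()].
#' @return An object of class `phase_flow_metrics`: a data frame with one
#'   row per (breath, ROI) and columns `pif`, `t_pif`, `lif`, `pef`,
#'   `t_pef`, `lef`, `flag_truncated`, `flag_reversal`.
#' @export
extract_metrics <- function(flow, volume, seg, delay = 0.5, window = 3.0,
                            estimator = c("ols", "endpoint")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(volume, "regional_volume_series"))
  if (!any(seg$cycles$complete)) {
    stop("no complete breath in record", call. = FALSE)
  }
  peaks <- detect_peak_flows(flow, seg)
  peaks$lif <- NA_real_
  peaks$lef <- NA_real_
  peaks$flag_truncated <- FALSE
  peaks$flag_reversal <- FALSE
  nf <- nrow(flow$series)
  for (i in seq_len(nrow(peaks))) {
    if (!peaks$complete[i]) next
    cyc <- seg$cycles[peaks$breath[i], ]
    clip <- c(cyc$start, cyc$end)
    roi <- peaks$roi[i]
    lif <- late_flow(volume, peaks$t_pif[i], delay, window, estimator,
                     roi = roi, clip = clip)
    lef <- late_flow(volume, peaks$t_pef[i], delay, window, estimator,
                     roi = roi, clip = clip)
    peaks$lif[i] <- lif$value
    peaks$lef[i] <- lef$value
    peaks$flag_truncated[i] <- lif$truncated || lef$truncated
    # phase split at the regional end-inspiratory volume maximum
    widx <- seq.int(cyc$start, cyc$end)
    imax <- widx[which.max(volume$series[widx, roi])]
    ks <- seq.int(cyc$start, min(cyc$end - 1L, nf))
    f <- flow$series[ks, roi]
    insp <- ks < imax
    peaks$flag_reversal[i] <- any(f[insp] < 0) || any(f[!insp] > 0)
  }
  class(peaks) <- c("phase_flow_metrics", "data.frame")
  peaks
}

#' Summarise phase metrics across breaths
#'
#' Arithmetic mean and sample standard deviation of each metric across the
#' complete breaths of a record, per ROI.
#'
#' @param metrics a `phase_flow_metrics` data frame.
#' @return An object of class `metrics_summary`: data frame with columns
#'   `roi`, `metric`, `mean`, `sd`, `n_breaths`.
#' @export
summarize_metrics <- function(metrics) {
  m <- metrics[metrics$complete, , drop = FALSE]
  if (nrow(m) == 0L) stop("no complete breath to summarise", call. = FALSE)
  out <- list()
  for (roi in unique(m$roi)) {
    mr <- m[m$roi == roi, , drop = FALSE]
    for (metric in c("pif", "lif", "pef", "lef")) {
      x <- mr[[metric]]
      out[[length(out) + 1L]] <- data.frame(
        roi = roi, metric = metric, mean = mean(x),
        sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
        n_breaths = length(x))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("metrics_summary", "data.frame")
  res
}
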