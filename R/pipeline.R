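#' Run the full EIT gas-flow analysis on a tomogram series
#'
#' Convenience wrapper chaining ROI extraction, breath segmentation on the
#' global impedance curve, tidal-amplitude calibration against the
#' ventilator tidal volume, backward-difference flow, phase-metric
#' extraction and the regional tidal-volume distribution.
#'
#' @param frames a [pixel_frame_series()] or an already extracted
#'   `regional_impedance_series`.
#' @param v_t ventilator tidal volume in ml.
#' @param rr respiratory rate hint in breaths/min.
#' @param layout a [roi_layout()] (ignored for pre-extracted input).
#' @param delay,window,estimator late-flow parameters, see [late_flow()].
#' @param renormalize passed to [tidal_distribution()].
#' @return list of class `eit_analysis` with elements `z`, `seg`, `z_t`,
#'   `volume`, `flow`, `metrics`, `summary`, `tidal`.
#' @export
analyze_record <- function(frames, v_t, rr = 8, layout = roi_layout(),
                           delay = 0.5, window = 3.0,
                           estimator = c("ols", "endpoint"),
                           renormalize = FALSE) {
  estimator <- match.arg(estimator)
  z <- if (inherits(frames, "regional_impedance_series")) frames
       else extract_roi_series(frames, layout)
  seg <- segment_breaths(z, rr_hint = rr)
  z_t <- compute_tidal_amplitude(z, seg)
  volume <- calibrate_volume(z, v_t = v_t, z_t = z_t)
  flow <- differentiate(volume)
  metrics <- extract_metrics(flow, volume, seg, delay = delay,
                             window = window, estimator = estimator)
  structure(list(z = z, seg = seg, z_t = z_t, volume = volume, flow = flow,
                 metrics = metrics, summary = summarize_metrics(metrics),
                 tidal = tidal_distribution(volume, seg,
                                            renormalize = renormalize)),
            class = "eit_analysis")
}

#' @export
print.eit_analysis <- function(x, ...) {
  cat(sprintf("<eit_analysis> %d complete breaths, Z_T = %.4g\n",
              sum(x$seg$cycles$complete), x$z_t))
  g <- x$summary[x$summary$roi == "global", ]
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  global %s: %8.2f +/- %.2f ml/s\n",
                toupper(g$metric[i]), g$mean[i], g$sd[i]))
  }
  print(x$tidal)
  invisible(x)
}

#' Compare EIT-derived and spirometric phase metrics breath by breath
#'
#' Pairs the global per-breath metrics of the two modalities by cycle
#' index and computes, per metric, the OLS regression of the EIT value on
#' the spirometry value plus the Bland-Altman statistics.
#'
#' @param eit_metrics `phase_flow_metrics` from [extract_metrics()].
#' @param spiro_metrics `phase_flow_metrics` from
#'   [extract_spiro_metrics()].
#' @return list of class `comparison_report`: per metric a list with
#'   `regression` ([linear_regression()]) and `bland_altman`
#'   ([bland_altman()]).
#' @export
compare_metrics <- function(eit_metrics, spiro_metrics) {
  e <- eit_metrics[eit_metrics$roi == "global" & eit_metrics$complete, ]
  s <- spiro_metrics[spiro_metrics$complete, ]
  common <- intersect(e$breath, s$breath)
  if (length(common) == 0L) {
    stop("unpaired records: no breath is complete in both modalities",
         call. = FALSE)
  }
  if (length(common) < 3L) {
    stop("need at least 3 paired complete breaths for the regression (got ",
         length(common), ")", call. = FALSE)
  }
  e <- e[match(common, e$breath), ]
  s <- s[match(common, s$breath), ]
  report <- lapply(c("pif", "lif", "pef", "lef"), function(metric) {
    x <- s[[metric]]
    y <- e[[metric]]
    list(regression = linear_regression(x, y),
         bland_altman = bland_altman(y, x),
         n = length(common))
  })
  names(report) <- c("pif", "lif", "pef", "lef")
  structure(report, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  for (metric in names(x)) {
    b <- x[[metric]]
    cat(toupper(metric), ": ", sep = "")
    cat(sprintf("EIT = %.3f * spiro %+.2f, r^2 = %.3f; bias %.2f, LoA [%.2f, %.2f] (n = %d)\n",
                b$regression$slope, b$regression$intercept,
                b$regression$r_squared, b$bland_altman$bias,
                b$bland_altman$loa_low, b$bland_altman$loa_high, b$n))
  }
  invisible(x)
}
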