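#' Phase metrics from the spirometric flow signal
#'
#' Extracts PIF, LIF, PEF and LEF from a directly measured airway flow
#' trace, using a breath segmentation transferred from the EIT record by
#' time (both modalities are recorded simultaneously on a common clock).
#' Peaks are found independently on the spirometry signal; because flow is
#' the measured quantity here, the late metrics are the arithmetic mean of
#' the flow samples in the window starting `delay` seconds after the
#' respective peak (equivalent to the endpoint slope of the integrated
#' volume). Windows are truncated to the breath and record with the same
#' 80%-coverage flag as [late_flow()].
#'
#' @param flow a [spiro_flow_series()].
#' @param seg a [breath_segmentation][segment_breaths()] (typically from
#'   the EIT arm; its cycle boundaries are mapped to the spirometry
#'   timebase).
#' @param delay,window late-flow window placement in s.
#' @return A `phase_flow_metrics` data frame with `roi = "global"`.
#' @export
extract_spiro_metrics <- function(flow, seg, delay = 0.5, window = 3.0) {
  stopifnot(inherits(flow, "spiro_flow_series"),
            inherits(seg, "breath_segmentation"))
  n <- length(flow$flow)
  tt <- flow$t0 + (seq_len(n) - 1) / flow$fs
  out <- list()
  for (b in seq_len(nrow(seg$cycles))) {
    cyc <- seg$cycles[b, ]
    t_start <- seg$t0 + (cyc$start - 1) / seg$fs
    t_end <- seg$t0 + (cyc$end - 1) / seg$fs
    j0 <- max(1L, snap_index(t_start, flow$t0, flow$fs))
    j1 <- min(n, snap_index(t_end, flow$t0, flow$fs) - 1L)
    if (!cyc$complete || j1 <= j0) {
      out[[length(out) + 1L]] <- data.frame(
        breath = b, roi = "global", complete = FALSE,
        pif = NA_real_, t_pif = NA_real_, pef = NA_real_, t_pef = NA_real_,
        lif = NA_real_, lef = NA_real_,
        flag_truncated = FALSE, flag_reversal = FALSE)
      next
    }
    ks <- seq.int(j0, j1)
    f <- flow$flow[ks]
    imax <- which.max(f)
    imin <- which.min(f)
    t_pif <- tt[ks[imax]]
    t_pef <- tt[ks[imin]]
    lif <- window_mean_flow(flow$flow, t_pif, delay, window,
                            flow$fs, flow$t0, clip = c(j0, j1))
    lef <- window_mean_flow(flow$flow, t_pef, delay, window,
                            flow$fs, flow$t0, clip = c(j0, j1))
    out[[length(out) + 1L]] <- data.frame(
      breath = b, roi = "global", complete = TRUE,
      pif = f[imax], t_pif = t_pif, pef = f[imin], t_pef = t_pef,
      lif = lif$value, lef = lef$value,
      flag_truncated = lif$truncated || lef$truncated,
      flag_reversal = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("phase_flow_metrics", "data.frame")
  res
}

# mean of flow samples in the snapped late window, truncated to clip/record
window_mean_flow <- function(x, t_peak, delay, window, fs, t0, clip) {
  n <- length(x)
  i0 <- snap_index(t_peak + delay, t0, fs)
  i1 <- snap_index(t_peak + delay + window, t0, fs)
  expected_n <- i1 - i0 + 1L
  lo <- max(1L, i0, clip[1L])
  hi <- min(n, i1, clip[2L])
  if (hi < lo) stop("empty late-flow window", call. = FALSE)
  idx <- seq.int(lo, hi)
  list(value = mean(x[idx]), n = length(idx), expected_n = expected_n,
       truncated = length(idx) < 0.8 * expected_n)
}

#' Estimate the clock lag between EIT and spirometry
#'
#' Maximises the cross-correlation between the global EIT flow (upsampled
#' to the spirometry rate by linear interpolation, no smoothing) and the
#' spirometric flow over a lag range of +/- `max_lag_s`.
#'
#' @param eit_flow a `regional_flow_series` (global column is used).
#' @param spiro_flow a `spiro_flow_series`.
#' @param max_lag_s half-width of the lag search range in s (defaults to
#'   one 7.5 s cycle). A correlation maximum on the boundary of the search
#'   range raises an "unalignable records" error.
#' @return estimated lag in s by which the spirometry record trails the
#'   EIT record (0 for perfectly synchronised records).
#' @export
estimate_lag <- function(eit_flow, spiro_flow, max_lag_s = 7.5) {
  stopifnot(inherits(eit_flow, "regional_flow_series"),
            inherits(spiro_flow, "spiro_flow_series"))
  fss <- spiro_flow$fs
  te <- series_times(eit_flow)
  s <- spiro_flow$flow
  ts_ <- spiro_flow$t0 + (seq_along(s) - 1) / fss
  e_up <- stats::approx(te, eit_flow$series[, "global"], xout = ts_,
                        rule = 1)$y
  keep <- !is.na(e_up)
  e_up <- e_up[keep]
  s <- s[keep]
  nmax <- as.integer(round(max_lag_s * fss))
  lags <- seq.int(-nmax, nmax)
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      a <- e_up[seq_len(length(e_up) - L)]
      b <- s[seq_len(length(s) - L) + L]
    } else {
      a <- e_up[seq_len(length(e_up) + L) - L]
      b <- s[seq_len(length(s) + L)]
    }
    if (length(a) < 10L || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(-Inf)
    }
    stats::cor(a, b)
  }, numeric(1))
  # periodic signals have near-equal correlation maxima one cycle apart
  # (edge trimming perturbs them by O(1e-3)); among near-ties prefer the
  # smallest absolute lag
  cand <- which(cc >= max(cc) - 0.01)
  best <- cand[which.min(abs(lags[cand]))]
  if (best == 1L || best == length(lags)) {
    stop("unalignable records: lag exceeds the search range", call. = FALSE)
  }
  lags[best] / fss
}

#' Pair EIT and spirometry metric summaries
#'
#' Pairs the record-level global means of the four phase metrics from the
#' two modalities. With `lag_correction = TRUE` the clock offset is first
#' estimated from the flow signals via [estimate_lag()] and reported
#' alongside the pairs.
#'
#' @param eit_summary,spiro_summary `metrics_summary` objects; the EIT
#'   summary's `"global"` rows are used.
#' @param lag_correction estimate the inter-record lag from the signals.
#' @param eit_flow,spiro_flow flow series, required when
#'   `lag_correction = TRUE`.
#' @param max_lag_s lag search half-range in s.
#' @return An object of class `paired_metric_set`: data frame with columns
#'   `metric`, `eit`, `spiro`; the estimated lag is in attribute `lag_s`.
#' @export
align_and_pair <- function(eit_summary, spiro_summary,
                           lag_correction = FALSE,
                           eit_flow = NULL, spiro_flow = NULL,
                           max_lag_s = 7.5) {
  lag_s <- 0
  if (lag_correction) {
    if (is.null(eit_flow) || is.null(spiro_flow)) {
      stop("lag correction requires the flow signals", call. = FALSE)
    }
    lag_s <- estimate_lag(eit_flow, spiro_flow, max_lag_s)
  }
  pick <- function(s, metric) {
    row <- s[s$roi == "global" & s$metric == metric, ]
    if (nrow(row) != 1L) stop("summary lacks a global ", metric, " row",
                              call. = FALSE)
    row$mean
  }
  metrics <- c("pif", "lif", "pef", "lef")
  pairs <- data.frame(
    metric = metrics,
    eit = vapply(metrics, pick, numeric(1), s = eit_summary),
    spiro = vapply(metrics, pick, numeric(1), s = spiro_summary),
    row.names = NULL)
  attr(pairs, "lag_s") <- lag_s
  class(pairs) <- c("paired_metric_set", "data.frame")
  pairs
}
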