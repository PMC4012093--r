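#' Segment a record into respiratory cycles
#'
#' Detects inspiration onsets as upward zero-crossings of the global
#' backward-difference flow and delimits respiratory cycles between
#' consecutive onsets. A refractory period of half the expected cycle
#' duration (from `rr_hint`) suppresses repeated triggering within one
#' breath.
#'
#' Detection strategy: the global flow is smoothed with a short centred
#' moving average (about 0.4 s) purely for onset detection; runs where the
#' smoothed flow exceeds 30% of its maximum mark candidate inspirations,
#' and each onset is placed at the upward zero-crossing of the raw flow
#' that initiates the run. On noise-free records this reduces to the exact
#' first positive raw-flow sample of each breath. The analysed signals are
#' never smoothed.
#'
#' Cycle completeness: a cycle bounded by two onsets is complete when its
#' duration is within +/-50% of the expected duration `60/rr_hint`; the
#' trailing cycle (last onset to end of record) is complete when it covers
#' at least 90% of the expected duration; a leading segment before the
#' first onset is emitted as an incomplete cycle.
#'
#' @param v a `regional_volume_series`, `regional_impedance_series`, or a
#'   numeric vector of the global signal (then `fs` is required). Onset
#'   detection is scale invariant, so segmentation may run on the
#'   uncalibrated impedance signal.
#' @param rr_hint expected respiratory rate in breaths/min (> 0).
#' @param fs sampling rate in Hz, only for numeric input.
#' @param t0 start time in s, only for numeric input.
#' @return An object of class `breath_segmentation` with a data frame
#'   `cycles` (`start`, `end` inclusive sample indices of the cycle window
#'   on the volume timebase, `complete`), the expected cycle duration, `fs`
#'   and `t0`.
#' @export
segment_breaths <- function(v, rr_hint, fs = NULL, t0 = 0) {
  if (is.numeric(v) && is.null(dim(v))) {
    g <- as.numeric(v)
    if (is.null(fs)) stop("`fs` is required for numeric input", call. = FALSE)
  } else {
    g <- v$series[, "global"]
    fs <- v$fs
    t0 <- v$t0
  }
  if (!is.numeric(rr_hint) || length(rr_hint) != 1L || rr_hint <= 0) {
    stop("`rr_hint` must be a positive respiratory rate", call. = FALSE)
  }
  n <- length(g)
  expected <- 60 / rr_hint
  if (n / fs < expected) {
    stop("record shorter than one expected respiratory cycle", call. = FALSE)
  }
  fl <- diff(g) * fs                       # fl[k] spans V[k] -> V[k+1]
  w <- max(3L, 2L * (round(0.4 * fs) %/% 2L) + 1L)  # odd smoothing width
  fls <- smooth_ma(fl, w)
  peak <- max(fls)
  if (peak <= 0) stop("no respiratory activity detected", call. = FALSE)
  theta <- 0.3 * peak
  above <- fls > theta
  run_starts <- which(above & !c(FALSE, above[-length(above)]))
  refractory <- 0.5 * expected
  back_max <- max(1L, floor(refractory * fs / 2))
  # trailing (causal) average for onset anchoring: it cannot leak the
  # coming inspiratory rise backwards in time, and its ~0.7 s width spans
  # about one cardiac period, suppressing the cardiac oscillation
  w_t <- max(3L, round(0.7 * fs))
  flt <- trailing_ma(fl, w_t)
  onsets <- integer(0)
  for (s in run_starts) {
    lo <- max(1L, s - back_max)
    neg <- which(flt[lo:s] <= 0)
    anchor <- if (length(neg)) lo + max(neg) - 1L else lo
    # the smoothed run can start a little before the raw crossing, so the
    # forward search for the first positive raw sample may pass `s`
    hi <- min(length(fl), s + w)
    pos <- which(fl[anchor:hi] > 0)
    k <- if (length(pos)) anchor + min(pos) - 1L else s
    if (length(onsets) == 0L || (k - onsets[length(onsets)]) / fs >= refractory) {
      onsets <- c(onsets, k)
    }
  }
  if (length(onsets) == 0L) {
    stop("no respiratory activity detected", call. = FALSE)
  }
  # cycle windows on the volume timebase: onset sample (the trough) up to
  # and including the next onset sample (shared trough), or end of record
  starts <- onsets
  ends <- c(onsets[-1L], n)
  dur <- (ends - starts) / fs
  complete <- ifelse(seq_along(starts) < length(starts),
                     dur >= 0.5 * expected & dur <= 1.5 * expected,
                     dur >= 0.9 * expected & dur <= 1.5 * expected)
  cycles <- data.frame(start = starts, end = ends, complete = complete)
  if (onsets[1L] > 1L) {
    cycles <- rbind(data.frame(start = 1L, end = onsets[1L], complete = FALSE),
                    cycles)
  }
  structure(list(cycles = cycles, expected_duration = expected,
                 fs = fs, t0 = t0, n_samples = n),
            class = "breath_segmentation")
}

#' @export
print.breath_segmentation <- function(x, ...) {
  cat(sprintf("<breath_segmentation> %d cycles (%d complete), expected %.3g s @ %g Hz\n",
              nrow(x$cycles), sum(x$cycles$complete), x$expected_duration, x$fs))
  invisible(x)
}

#' Onset times of the segmented breaths
#'
#' @param seg a `breath_segmentation`.
#' @param complete_only drop incomplete cycles.
#' @return numeric vector of inspiration-onset times in s.
#' @export
breath_onsets <- function(seg, complete_only = FALSE) {
  cyc <- seg$cycles
  if (complete_only) cyc <- cyc[cyc$complete, , drop = FALSE]
  seg$t0 + (cyc$start - 1) / seg$fs
}

# trailing moving average over the last w samples (shorter at the start)
trailing_ma <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - w + 1L)
  (cs[seq_len(n) + 1L] - cs[lo]) / (seq_len(n) - lo + 1L)
}

# centred moving average with shrinking windows at the edges
smooth_ma <- function(x, w) {
  h <- w %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
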