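#' Ordinary least-squares regression for method comparison
#'
#' Unweighted OLS of `y` on `x` with the squared Pearson correlation as
#' r-squared, matching the reported form `metric_EIT = a * metric_spiro + b`
#' (pass the spirometry values as `x` and the EIT values as `y`).
#'
#' @param x,y paired numeric vectors, `n >= 3`, `var(x) > 0`.
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("var(x) = 0: regression is undefined",
                               call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.4g * x %+.4g, r^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Bland-Altman analysis of two measurement methods
#'
#' Differences `d = x - y` are analysed against pair means `m = (x + y)/2`:
#' bias is the mean difference, the 95% limits of agreement are
#' `bias +/- 1.96 * sd(d)` (sample sd), and the proportional error is
#' quantified as the OLS slope of `d` on `m` together with its two-sided
#' p-value.
#'
#' @param x,y paired numeric vectors, `n >= 2`.
#' @return An object of class `bland_altman_result`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `proportional_slope`,
#'   `proportional_p`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  slope <- NA_real_
  p <- NA_real_
  if (stats::var(m) > 0) {
    slope <- stats::cov(m, d) / stats::var(m)
    if (n > 2L) {
      resid <- d - (mean(d) + slope * (m - mean(m)))
      s2 <- sum(resid^2) / (n - 2L)
      se <- sqrt(s2 / sum((m - mean(m))^2))
      p <- if (se == 0) {
        if (slope == 0) 1 else 0
      } else {
        2 * stats::pt(-abs(slope / se), df = n - 2L)
      }
    }
  } else if (stats::sd(d) == 0) {
    slope <- 0
  }
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 proportional_slope = slope, proportional_p = p, n = n),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("bias %.4g, LoA [%.4g, %.4g], proportional slope %.4g (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$proportional_slope, x$n))
  invisible(x)
}

#' Regional distribution of the tidal volume
#'
#' Per complete breath, the percentage of the global tidal amplitude
#' attributed to each sub-ROI:
#' `100 * (max - min of V_ROI within the cycle) / (max - min of V_global)`.
#' The record value is the mean across breaths.
#'
#' Because regional extrema need not be simultaneous, the three
#' percentages may sum to more than 100 when the regional time constants
#' differ; with synchronous regions they sum to exactly 100. Set
#' `renormalize = TRUE` to rescale each breath's percentages to a 100% sum
#' instead.
#'
#' @param v a `regional_volume_series` (an uncalibrated impedance series
#'   works too; the ratio is scale free).
#' @param seg the record's [breath_segmentation][segment_breaths()].
#' @param renormalize divide by the sum of the regional amplitudes instead
#'   of the global amplitude.
#' @return An object of class `tidal_distribution`: list with `per_breath`
#'   (data frame of percentages per complete breath) and `mean` (named
#'   vector ventral/middle/dorsal).
#' @export
tidal_distribution <- function(v, seg, renormalize = FALSE) {
  stopifnot(inherits(seg, "breath_segmentation"))
  cyc <- seg$cycles[seg$cycles$complete, , drop = FALSE]
  if (nrow(cyc) == 0L) stop("no complete breath in record", call. = FALSE)
  sub <- c("ventral", "middle", "dorsal")
  rows <- lapply(seq_len(nrow(cyc)), function(i) {
    idx <- cyc$start[i]:cyc$end[i]
    amp <- vapply(sub, function(r) {
      w <- v$series[idx, r]
      max(w) - min(w)
    }, numeric(1))
    g <- v$series[idx, "global"]
    amp_g <- max(g) - min(g)
    if (amp_g <= 0) stop("zero global tidal amplitude", call. = FALSE)
    denom <- if (renormalize) sum(amp) else amp_g
    pct <- 100 * amp / denom
    data.frame(breath = i, ventral = pct[["ventral"]],
               middle = pct[["middle"]], dorsal = pct[["dorsal"]],
               total = sum(pct))
  })
  per_breath <- do.call(rbind, rows)
  structure(list(per_breath = per_breath,
                 mean = colMeans(per_breath[, sub]),
                 renormalized = renormalize),
            class = "tidal_distribution")
}

#' @export
print.tidal_distribution <- function(x, ...) {
  cat(sprintf("tidal volume distribution over %d breaths%s:\n",
              nrow(x$per_breath),
              if (x$renormalized) " (renormalised to 100%)" else ""))
  cat(sprintf("  ventral %.1f%%  middle %.1f%%  dorsal %.1f%%\n",
              x$mean[["ventral"]], x$mean[["middle"]], x$mean[["dorsal"]]))
  invisible(x)
}
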