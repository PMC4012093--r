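#' Region-of-interest partition of the tomogram pixel matrix
#'
#' Defines which rows of the pixel matrix belong to the ventral, middle and
#' dorsal regions of interest and which rows are excluded from evaluation.
#' Row 0 is the most ventral row, the last row the most dorsal one; a
#' transposed export can be accommodated by passing explicit ranges.
#'
#' The default partition on a 32 x 32 matrix assigns three 8 x 32 strips to
#' the ventral, middle and dorsal ROI and excludes the dorsal-most 8 x 32
#' strip, which contains no lung in the supine pig. The global ROI is the
#' union of the three sub-ROIs (the ventral 24 x 32 pixels).
#'
#' @param n_rows,n_cols dimensions of the pixel matrix.
#' @param ventral,middle,dorsal,excluded half-open, 0-based row ranges
#'   `c(from, to)`. Defaults split the matrix into four equal strips.
#' @return An object of class `roi_layout`.
#' @examples
#' roi_layout()                      # canonical 32 x 32 partition
#' roi_layout(n_rows = 8, n_cols = 8) # reduced test matrix
#' @export
roi_layout <- function(n_rows = 32L, n_cols = 32L,
                       ventral = NULL, middle = NULL, dorsal = NULL,
                       excluded = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 4L || n_cols < 1L) {
    stop("matrix must have at least 4 rows and 1 column", call. = FALSE)
  }
  q <- n_rows %/% 4L
  if (is.null(ventral)) ventral <- c(0L, q)
  if (is.null(middle)) middle <- c(q, 2L * q)
  if (is.null(dorsal)) dorsal <- c(2L * q, 3L * q)
  if (is.null(excluded)) excluded <- c(3L * q, n_rows)
  ranges <- list(ventral = as.integer(ventral), middle = as.integer(middle),
                 dorsal = as.integer(dorsal), excluded = as.integer(excluded))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] < 0L || r[2] > n_rows || r[1] > r[2]) {
      stop("invalid row range for ", nm, " ROI", call. = FALSE)
    }
  }
  covered <- integer(0)
  for (r in ranges) covered <- c(covered, seq_len(r[2] - r[1]) - 1L + r[1])
  if (anyDuplicated(covered)) {
    stop("ROI row ranges must be disjoint", call. = FALSE)
  }
  if (!setequal(covered, seq_len(n_rows) - 1L)) {
    stop("ROI row ranges must cover all ", n_rows, " matrix rows",
         call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, ranges = ranges),
            class = "roi_layout")
}

#' @export
print.roi_layout <- function(x, ...) {
  cat("<roi_layout> ", x$n_rows, "x", x$n_cols, " pixel matrix\n", sep = "")
  for (nm in names(x$ranges)) {
    r <- x$ranges[[nm]]
    cat(sprintf("  %-8s rows [%d, %d)\n", nm, r[1], r[2]))
  }
  invisible(x)
}

# 1-based matrix row indices of one ROI ("global" = union of the sub-ROIs)
roi_row_indices <- function(layout, roi) {
  if (roi == "global") {
    return(sort(unlist(lapply(c("ventral", "middle", "dorsal"),
                              roi_row_indices, layout = layout))))
  }
  r <- layout$ranges[[roi]]
  if (r[1] == r[2]) return(integer(0))
  seq.int(r[1] + 1L, r[2])
}

# names of the four evaluated ROIs, in canonical order
roi_names <- function() c("global", "ventral", "middle", "dorsal")
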