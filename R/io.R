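# File formats: plain text, full double precision ("%.17g"), "#"-prefixed
# key=value header lines. All volumes ml, times s, flows ml/s.

fmt <- function(x) sprintf("%.17g", x)

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(\\S+)", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Write / read a tomogram series as delimited text
#'
#' One data row per frame holding `rows * cols` pixel values in row-major
#' order (row 0 = most ventral), preceded by `# fs_hz=`, `# matrix=<rows>x<cols>`
#' and `# t0_s=` header lines.
#'
#' @param frames a [pixel_frame_series()].
#' @param path file path.
#' @return `read_eit_frames()` returns a `pixel_frame_series`;
#'   `write_eit_frames()` returns `path` invisibly.
#' @export
write_eit_frames <- function(frames, path) {
  stopifnot(inherits(frames, "pixel_frame_series"))
  d <- dim(frames$frames)
  vals <- matrix(fmt(aperm(frames$frames, c(3, 2, 1))), nrow = d[2] * d[3])
  lines <- c(sprintf("# fs_hz=%s", fmt(frames$fs)),
             sprintf("# matrix=%dx%d", d[2], d[3]),
             sprintf("# t0_s=%s", fmt(frames$t0)),
             apply(vals, 2L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_eit_frames
#' @export
read_eit_frames <- function(path) {
  lines <- readLines(path)
  kv <- parse_header(lines)
  if (is.null(kv$fs_hz) || is.null(kv$matrix)) {
    stop("missing '# fs_hz=' or '# matrix=' header in ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(kv$matrix, "x")[[1]])
  data <- lines[!grepl("^#", lines)]
  data <- data[nzchar(trimws(data))]
  v <- scan(text = data, quiet = TRUE)
  n_frames <- length(v) / (dims[1] * dims[2])
  if (n_frames != round(n_frames)) {
    stop(sprintf("malformed frame file %s: %d values do not fill %dx%d frames",
                 path, length(v), dims[1], dims[2]), call. = FALSE)
  }
  arr <- aperm(array(v, dim = c(dims[2], dims[1], n_frames)), c(3, 2, 1))
  pixel_frame_series(arr, fs = as.numeric(kv$fs_hz),
                     t0 = as.numeric(kv$t0_s %||% 0))
}

#' Write / read a spirometric flow trace
#'
#' Two-column delimited text (`time_s`, `flow_ml_s`), inspiratory flow
#' positive, with a `# fs_hz=` header line.
#'
#' @param spiro a [spiro_flow_series()].
#' @param path file path.
#' @return `read_spiro()` returns a `spiro_flow_series`.
#' @export
write_spiro <- function(spiro, path) {
  stopifnot(inherits(spiro, "spiro_flow_series"))
  tt <- spiro$t0 + (seq_along(spiro$flow) - 1) / spiro$fs
  writeLines(c(sprintf("# fs_hz=%s", fmt(spiro$fs)),
               sprintf("# t0_s=%s", fmt(spiro$t0)),
               "time_s\tflow_ml_s",
               paste(fmt(tt), fmt(spiro$flow), sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_spiro
#' @export
read_spiro <- function(path) {
  lines <- readLines(path)
  kv <- parse_header(lines)
  if (is.null(kv$fs_hz)) {
    stop("missing '# fs_hz=' header in ", path, call. = FALSE)
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  spiro_flow_series(tab$flow_ml_s, fs = as.numeric(kv$fs_hz),
                    t0 = as.numeric(kv$t0_s %||% 0))
}

#' Write / read pre-extracted regional impedance curves
#'
#' Long-format delimited table with columns `time_s`, `roi`, `z` and a
#' `# fs_hz=` header. When the table carries only the three sub-ROIs the
#' global curve is reconstructed as their sum.
#'
#' @param z a `regional_impedance_series`.
#' @param path file path.
#' @return `read_regional_series()` returns a `regional_impedance_series`.
#' @export
write_regional_series <- function(z, path) {
  tt <- series_times(z)
  rois <- colnames(z$series)
  lines <- c(sprintf("# fs_hz=%s", fmt(z$fs)),
             sprintf("# t0_s=%s", fmt(z$t0)),
             "time_s\troi\tz")
  for (roi in rois) {
    lines <- c(lines, paste(fmt(tt), roi, fmt(z$series[, roi]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_regional_series
#' @export
read_regional_series <- function(path) {
  lines <- readLines(path)
  kv <- parse_header(lines)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("time_s", "roi", "z") %in% names(tab))) {
    stop("regional series table needs columns time_s, roi, z", call. = FALSE)
  }
  tt <- sort(unique(tab$time_s))
  fs <- if (!is.null(kv$fs_hz)) as.numeric(kv$fs_hz)
        else 1 / stats::median(diff(tt))
  series <- matrix(NA_real_, nrow = length(tt), ncol = 4L,
                   dimnames = list(NULL, roi_names()))
  for (roi in intersect(unique(tab$roi), roi_names())) {
    sub <- tab[tab$roi == roi, ]
    series[, roi] <- sub$z[order(sub$time_s)]
  }
  if (anyNA(series[, "global"])) {
    series[, "global"] <- rowSums(series[, c("ventral", "middle", "dorsal")])
  }
  if (anyNA(series)) {
    stop("regional series table must provide ventral, middle and dorsal curves",
         call. = FALSE)
  }
  new_regional_series(series, fs = fs, t0 = tt[1],
                      class = "regional_impedance_series")
}

#' Write a data frame as a TSV at full precision
#'
#' @param x data frame.
#' @param path file path.
#' @keywords internal
#' @export
write_tsv <- function(x, path) {
  for (col in names(x)) {
    if (is.double(x[[col]])) x[[col]] <- fmt(x[[col]])
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` comments and `[section]` headers
#' are ignored. Values are parsed as numbers or logicals where possible.
#'
#' @param path file path.
#' @param cfg named list of configuration values.
#' @return `read_run_config()` returns a named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|\\[|$)", lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*?)\\s*$",
                                ln))[[1]]
    if (length(m) != 3L) next
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    cfg[[m[2]]] <- if (!is.na(num)) num
                   else if (val %in% c("TRUE", "FALSE", "true", "false"))
                     as.logical(toupper(val))
                   else val
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    v <- if (is.numeric(v)) fmt(v) else as.character(v)
    paste0(k, " = ", v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
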