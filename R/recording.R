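#' Acceleration recording container
#'
#' An `fm_recording` holds a dual 3-axis accelerometer recording: six ordered
#' acceleration channels in units of g (sensor 1 x, y, z then sensor 2
#' x, y, z) sampled at a common fixed rate, with optional ground-truth
#' event-interval annotations (maternal perception of fetal movement).
#'
#' @param channels numeric matrix, one column per channel in the order
#'   `s1x, s1y, s1z, s2x, s2y, s2z`; values in g.
#' @param sample_rate sampling rate in samples/second (default 100).
#' @param annotations optional data frame with columns `start_s`, `end_s`,
#'   `label`; intervals in seconds, half-open, within the recording.
#' @return an object of class `fm_recording` with elements `channels`,
#'   `sample_rate`, `n_samples`, `annotations`.
#' @export
fm_recording <- function(channels, sample_rate = 100, annotations = NULL) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 6L)
    stop("format error: a recording needs exactly 6 acceleration channels, got ",
         ncol(channels))
  if (!is.numeric(channels) || anyNA(channels) || any(!is.finite(channels)))
    stop("channels must be finite numeric values in g")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  colnames(channels) <- c("s1x", "s1y", "s1z", "s2x", "s2y", "s2z")
  n <- nrow(channels)
  dur <- n / sample_rate
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    req <- c("start_s", "end_s")
    if (!all(req %in% names(annotations)))
      stop("annotations need columns start_s and end_s")
    if (is.null(annotations$label)) annotations$label <- "FM_perceived"
    bad <- annotations$start_s < 0 | annotations$start_s >= annotations$end_s |
      annotations$end_s > dur + 1e-9
    if (any(bad))
      stop("invalid annotation interval(s): row ", which(bad)[1],
           " must satisfy 0 <= start < end <= ", format(dur))
  }
  structure(list(channels = channels, sample_rate = sample_rate,
                 n_samples = n, annotations = annotations),
            class = "fm_recording")
}

#' @export
print.fm_recording <- function(x, ...) {
  cat(sprintf("fm_recording: %d samples x 6 channels @ %g Hz (%.1f s)\n",
              x$n_samples, x$sample_rate, x$n_samples / x$sample_rate))
  n_ann <- if (is.null(x$annotations)) 0L else nrow(x$annotations)
  cat(sprintf("  annotations: %d event interval(s)\n", n_ann))
  invisible(x)
}

detect_delim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Load a recording from delimited text
#'
#' Reads a comma- or tab-delimited file (autodetected) with a header row and
#' columns `time_s, s1x, s1y, s1z, s2x, s2y, s2z`. With `dialect =
#' "raw_counts"` each acceleration value is an integer sensor count amplified
#' by 10,000 for upload; values are converted to g by dividing by 10,000 and
#' by the sensor sensitivity of 4096 counts/g.
#'
#' @param path recording file path.
#' @param dialect `"g_units"` (values already in g) or `"raw_counts"`.
#' @param annotations_path optional sidecar annotation file with header
#'   `start_s, end_s, label`.
#' @param sample_rate sampling rate in Hz; if `NULL`, inferred from the
#'   median spacing of the time column.
#' @return [fm_recording()] object.
#' @export
load_recording <- function(path, dialect = c("g_units", "raw_counts"),
                           annotations_path = NULL, sample_rate = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("format error: ", path, " has no data rows")
  delim <- detect_delim(lines[1])
  header <- trimws(strsplit(lines[1], delim, fixed = TRUE)[[1]])
  if (length(header) != 7L)
    stop("format error: expected 7 columns (time_s + 6 channels), got ",
         length(header))
  cells <- strsplit(lines[-1], delim, fixed = TRUE)
  ncell <- lengths(cells)
  if (any(ncell != 7L))
    stop("format error: line ", which(ncell != 7L)[1] + 1L,
         " has ", ncell[ncell != 7L][1], " fields (expected 7)")
  m <- matrix(suppressWarnings(as.numeric(trimws(unlist(cells)))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1]
    stop("parse error: non-numeric value on line ", bad + 1L)
  }
  acc <- m[, 2:7, drop = FALSE]
  if (dialect == "raw_counts") acc <- acc / 10000 / 4096
  if (is.null(sample_rate)) {
    dt <- stats::median(diff(m[, 1]))
    sample_rate <- if (is.finite(dt) && dt > 0) 1 / dt else 100
  }
  ann <- if (!is.null(annotations_path)) load_annotations(annotations_path)
  fm_recording(acc, sample_rate = sample_rate, annotations = ann)
}

#' Load an annotation file
#'
#' Delimited text (comma or tab) with header `start_s, end_s, label`.
#'
#' @param path annotation file path.
#' @return data frame with columns `start_s`, `end_s`, `label`.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  ann <- utils::read.table(path, header = TRUE, sep = detect_delim(first),
                           strip.white = TRUE, stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s") %in% names(ann)))
    stop("format error: annotation file needs columns start_s, end_s")
  if (is.null(ann$label)) ann$label <- "FM_perceived"
  ann
}

#' Write a recording (and its annotations) as delimited text
#'
#' @param rec [fm_recording()] object.
#' @param path output path for the recording table (CSV).
#' @param annotations_path optional output path for the annotation table.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, annotations_path = NULL) {
  stopifnot(inherits(rec, "fm_recording"))
  t <- (seq_len(rec$n_samples) - 1L) / rec$sample_rate
  df <- data.frame(time_s = t, rec$channels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(annotations_path)) {
    ann <- rec$annotations
    if (is.null(ann))
      ann <- data.frame(start_s = numeric(0), end_s = numeric(0),
                        label = character(0))
    utils::write.csv(ann, annotations_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Segment a recording into non-overlapping analysis windows
#'
#' Tiles each channel with consecutive, non-overlapping windows of
#' `window_seconds` (2.56 s at the 100 Hz default rate, i.e. 256 samples,
#' the unit of all downstream classification). A trailing partial segment is
#' discarded. Window `k` (0-based) covers samples `[k*w, (k+1)*w)`.
#'
#' @param rec [fm_recording()] object.
#' @param window_seconds window length in seconds (default 2.56).
#' @return a list with `windows` (array `window_samples x n_windows x 6`),
#'   `n_windows`, `window_samples`, `window_seconds`, `start_s` (window start
#'   times in seconds), `sample_rate`.
#' @export
segment_windows <- function(rec, window_seconds = 2.56) {
  stopifnot(inherits(rec, "fm_recording"))
  w <- as.integer(round(window_seconds * rec$sample_rate))
  if (w < 1L) stop("window_seconds too small for the sample rate")
  if (rec$n_samples < w)
    stop("empty result: recording (", rec$n_samples,
         " samples) is shorter than one window (", w, " samples)")
  k <- rec$n_samples %/% w
  used <- rec$channels[seq_len(k * w), , drop = FALSE]
  arr <- array(used, dim = c(w, k, 6L))
  list(windows = arr, n_windows = k, window_samples = w,
       window_seconds = window_seconds,
       start_s = (seq_len(k) - 1L) * w / rec$sample_rate,
       sample_rate = rec$sample_rate)
}
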