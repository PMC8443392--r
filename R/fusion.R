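#' Six-axis binary mask fusion for one window
#'
#' Combines the per-axis detector outcomes of a window into the binary mask
#' `M(1:6)` (1 = FM on that axis, 0 = non-FM) and the fused window label: if
#' one or more of the six axes is identified as FM the window is FM,
#' otherwise non-FM. A suppressed axis (gate) contributes a fixed 0; an
#' ARTIFACT window has an all-zero mask.
#'
#' @param axis_decisions list of exactly 6 entries, one per axis: an
#'   `axis_decision` (from [omp_classify()] / [lms_classify()]) for
#'   CANDIDATE axes, or `NULL`/`"SUPPRESSED"` for suppressed axes.
#' @param gate [gate_window()] outcome for the same window.
#' @return an object of class `window_decision`: `window_index`, `mask`
#'   (integer vector of 6 bits), `fused_label` (`"FM"`/`"NON_FM"`),
#'   `gate_flag`.
#' @export
fuse_masks <- function(axis_decisions, gate) {
  stopifnot(inherits(gate, "gate_outcome"))
  if (length(axis_decisions) != 6L)
    stop("contract error: exactly 6 axis entries expected, got ",
         length(axis_decisions))
  mask <- integer(6L)
  for (a in seq_len(6L)) {
    d <- axis_decisions[[a]]
    if (gate$window_flag == "PASS" && gate$per_axis[a] == "CANDIDATE" &&
        inherits(d, "axis_decision") && identical(d$label, "FM"))
      mask[a] <- 1L
  }
  structure(list(window_index = gate$window_index, mask = mask,
                 fused_label = if (any(mask == 1L)) "FM" else "NON_FM",
                 gate_flag = gate$window_flag),
            class = "window_decision")
}

#' @export
print.window_decision <- function(x, ...) {
  cat(sprintf("window %s [%s]: mask %s -> %s\n",
              format(x$window_index), x$gate_flag,
              paste(x$mask, collapse = ""), x$fused_label))
  invisible(x)
}

#' Merge per-window FM decisions into detected event intervals
#'
#' Maximal runs of consecutive FM-labelled windows become one detected
#' event interval `[first_start, last_start + window_seconds)`.
#'
#' @param decisions either the `decisions` data frame of an
#'   [run_detection()] result (columns `window_index`, `start_s`,
#'   `fused_label`, ordered by window), or a list of `window_decision`
#'   objects (then `window_seconds` spacing defines start times).
#' @param window_seconds window length in seconds.
#' @return data frame with columns `start_s`, `end_s` (possibly 0 rows).
#' @export
decisions_to_events <- function(decisions, window_seconds = 2.56) {
  if (is.data.frame(decisions)) {
    fm <- decisions$fused_label == "FM"
    starts <- decisions$start_s
  } else {
    fm <- vapply(decisions, function(d) identical(d$fused_label, "FM"), logical(1))
    idx <- vapply(decisions, function(d) as.numeric(d$window_index), numeric(1))
    starts <- idx * window_seconds
  }
  if (!any(fm))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  r <- rle(fm)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_s = starts[begs[keep]],
             end_s = starts[ends[keep]] + window_seconds)
}

# any nonzero temporal overlap of half-open intervals
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Event-level detection metrics: TDR and PPV
#'
#' Scores detected event intervals against annotated maternal-perception
#' intervals. `TMF` is the number of annotated (true maternal FM) events; an
#' annotated event counts once in `DME` (detected maternal events) if at
#' least one detected event overlaps it; `FD` (false detections) is the
#' number of detected events overlapping no annotated event. Then
#' `TDR = 100 * DME / TMF` and `PPV = 100 * DME / (DME + FD)`, both rounded
#' half-up to 2 decimals; `PPV` is defined as 0 when nothing was detected.
#' Any nonzero temporal overlap matches, and multiple detected events over
#' one annotation count as a single `DME` with no extra `FD`.
#'
#' @param detected data frame of detected intervals (`start_s`, `end_s`),
#'   e.g. from [decisions_to_events()].
#' @param truth data frame of annotated intervals (`start_s`, `end_s`);
#'   must be non-empty.
#' @param subject optional subject tag carried into the report.
#' @return an object of class `fm_metrics`: list with `TMF`, `DME`, `FD`,
#'   `TDR`, `PPV`, `subject`.
#' @export
compute_metrics <- function(detected, truth, subject = NA) {
  truth <- as.data.frame(truth)
  detected <- as.data.frame(detected)
  TMF <- nrow(truth)
  if (TMF == 0L)
    stop("metrics undefined: no annotated events (TMF == 0)")
  nd <- nrow(detected)
  if (nd > 0L) {
    hit <- outer(seq_len(TMF), seq_len(nd), function(i, j)
      intervals_overlap(truth$start_s[i], truth$end_s[i],
                        detected$start_s[j], detected$end_s[j]))
    DME <- sum(apply(hit, 1L, any))
    FD <- sum(!apply(hit, 2L, any))
  } else {
    DME <- 0L; FD <- 0L
  }
  TDR <- round_half_up(100 * DME / TMF)
  PPV <- if (DME + FD == 0L) 0 else round_half_up(100 * DME / (DME + FD))
  structure(list(subject = subject, TMF = TMF, DME = DME, FD = FD,
                 TDR = TDR, PPV = PPV),
            class = "fm_metrics")
}

#' Metrics directly from event counts
#'
#' Convenience constructor for an [compute_metrics()]-style report from
#' already-tallied counts (e.g. a published results table).
#'
#' @param TMF,DME,FD event counts; `0 <= DME <= TMF`.
#' @param subject optional subject tag.
#' @return an object of class `fm_metrics`.
#' @export
metrics_from_counts <- function(TMF, DME, FD, subject = NA) {
  if (TMF == 0L) stop("metrics undefined: TMF == 0")
  if (DME < 0 || DME > TMF || FD < 0)
    stop("invalid counts: need 0 <= DME <= TMF and FD >= 0")
  TDR <- round_half_up(100 * DME / TMF)
  PPV <- if (DME + FD == 0) 0 else round_half_up(100 * DME / (DME + FD))
  structure(list(subject = subject, TMF = TMF, DME = DME, FD = FD,
                 TDR = TDR, PPV = PPV),
            class = "fm_metrics")
}

#' @export
print.fm_metrics <- function(x, ...) {
  cat(sprintf("FM detection metrics%s\n",
              if (is.na(x$subject)) "" else paste0(" (subject ", x$subject, ")")))
  cat(sprintf("  TMF = %d, DME = %d, FD = %d\n", x$TMF, x$DME, x$FD))
  cat(sprintf("  TDR = %.2f%%, PPV = %.2f%%\n", x$TDR, x$PPV))
  invisible(x)
}

#' @export
as.data.frame.fm_metrics <- function(x, ...) {
  data.frame(subject = x$subject, TMF = x$TMF, DME = x$DME, FD = x$FD,
             TDR = x$TDR, PPV = x$PPV)
}

#' Write one or more metrics reports as a delimited table
#'
#' Columns `subject, TMF, DME, FD, TDR, PPV`, mirroring the usual
#' per-subject results-table layout.
#'
#' @param reports an `fm_metrics` object or a list of them.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(reports, path) {
  if (inherits(reports, "fm_metrics")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
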