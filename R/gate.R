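#' Amplitude gate thresholds
#'
#' The three empirical amplitude bounds of abdominal accelerometry: fetal
#' movement peaks lie roughly in (A1, A2) = (0.015, 0.06) g, maternal
#' respiration below A1, other background noise in (A2, A3), and maternal
#' body-movement artifacts (cough, laughter, posture shifts) above
#' A3 = 0.1 g.
#'
#' @param a1 FM lower bound in g (default 0.015).
#' @param a2 FM upper bound in g (default 0.06).
#' @param a3 artifact bound in g (default 0.1).
#' @return an object of class `gate_thresholds`.
#' @export
gate_thresholds <- function(a1 = 0.015, a2 = 0.06, a3 = 0.1) {
  if (!(0 < a1 && a1 < a2 && a2 < a3))
    stop("invalid thresholds: need 0 < A1 < A2 < A3")
  structure(list(a1 = a1, a2 = a2, a3 = a3), class = "gate_thresholds")
}

#' Peak amplitude of a window
#'
#' @param w numeric vector (one preprocessed analysis window).
#' @return `max(abs(w))` in g.
#' @export
peak_amplitude <- function(w) max(abs(as.numeric(w)))

#' Amplitude-threshold artifact gate for one window
#'
#' Pre-identification of maternal artifacts and FM candidates from the six
#' per-axis peak amplitudes of a preprocessed window. If any axis peak
#' exceeds A3 the whole window is a characteristic artifact: every axis is
#' suppressed and classification is skipped. Otherwise each axis is a
#' CANDIDATE (passed to the detector) iff its peak lies strictly inside
#' (A1, A2); peaks below A1 (respiration) or between A2 and A3 (background
#' noise) contribute a fixed 0 to the mask fuser. Peaks exactly equal to a
#' threshold fall into the non-candidate branch.
#'
#' @param peaks numeric vector of 6 non-negative per-axis peak amplitudes (g).
#' @param th [gate_thresholds()] object.
#' @param window_index optional ordinal carried through to the outcome.
#' @return an object of class `gate_outcome`: list with `window_flag`
#'   (`"ARTIFACT"` or `"PASS"`), `per_axis` (6 values `"CANDIDATE"` /
#'   `"SUPPRESSED"`), `peaks`, `window_index`.
#' @export
gate_window <- function(peaks, th = gate_thresholds(), window_index = NA_integer_) {
  peaks <- as.numeric(peaks)
  if (length(peaks) != 6L)
    stop("contract error: exactly 6 per-axis peaks expected, got ", length(peaks))
  if (any(peaks < 0)) stop("domain error: peak amplitudes must be non-negative")
  stopifnot(inherits(th, "gate_thresholds"))
  if (any(peaks > th$a3)) {
    flag <- "ARTIFACT"
    per_axis <- rep("SUPPRESSED", 6L)
  } else {
    flag <- "PASS"
    per_axis <- ifelse(peaks > th$a1 & peaks < th$a2, "CANDIDATE", "SUPPRESSED")
  }
  structure(list(window_flag = flag, per_axis = per_axis, peaks = peaks,
                 window_index = window_index),
            class = "gate_outcome")
}
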