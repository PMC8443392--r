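#' Scalar Kalman filter parameters
#'
#' Parameters of the per-axis scalar state-space model
#' `x[k] = A x[k-1] + w[k]` (process noise variance `Q`; the exogenous input
#' term is fixed to zero) with measurement `y[k] = H x[k] + v[k]`
#' (measurement noise variance `R`). The default is a random-walk model
#' (`A = H = 1`) whose process variance is chosen so that transients in the
#' fetal-movement band (2-10 Hz) pass with near-unity gain while wideband
#' sensor noise is attenuated.
#'
#' @param A state transition scalar (default 1).
#' @param H measurement scalar (default 1).
#' @param Q process-noise variance in g^2 (default 5e-5).
#' @param R measurement-noise variance in g^2 (must be > 0).
#' @param x0 initial state estimate (default: first sample of the window).
#' @param P0 initial estimate variance (default: `R`).
#' @return an object of class `kalman_params`.
#' @export
kalman_params <- function(A = 1, H = 1, Q = 5e-5, R, x0 = NULL, P0 = NULL) {
  if (missing(R)) stop("parameter error: R (measurement-noise variance) is required")
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("parameter error: R must be > 0")
  if (Q < 0) stop("parameter error: Q must be >= 0")
  if (is.null(P0)) P0 <- R
  if (P0 < 0) stop("parameter error: P0 must be >= 0")
  structure(list(A = A, H = H, Q = Q, R = R, x0 = x0, P0 = P0),
            class = "kalman_params")
}

#' DC correction by first differences
#'
#' Replaces a window by its sample-to-sample change `S[k] - S[k-1]`, which
#' cancels any constant offset. The first output sample is 0 so the window
#' length is preserved. Note that differencing also rescales a sinusoid at
#' frequency f by `2 sin(pi f / fs)`; the pipeline therefore defaults to
#' amplitude-preserving baseline removal (`dc_method = "detrend"`) for the
#' gated path, and this operator is available via `dc_method = "diff"`.
#'
#' @param w numeric vector (one analysis window).
#' @return numeric vector of the same length.
#' @export
remove_dc <- function(w) {
  w <- as.numeric(w)
  if (length(w) == 0L) return(w)
  c(0, diff(w))
}

#' Kalman-filter reconstruction of one window
#'
#' Runs the standard scalar predict/update recursion over the samples of a
#' window: predict `x^- = A x`, `P^- = A^2 P + Q`; gain
#' `K = P^- H / (H^2 P^- + R)`; update `x = x^- + K (y - H x^-)`,
#' `P = (1 - K H) P^-`. The sequence of updated state estimates is the
#' reconstructed window; the error-variance trace is attached as attribute
#' `"P"`.
#'
#' @param w numeric vector (one analysis window), the measurements `y`.
#' @param p [kalman_params()] object.
#' @return filtered numeric vector with attribute `P`.
#' @export
kalman_filter <- function(w, p) {
  stopifnot(inherits(p, "kalman_params"))
  w <- as.numeric(w)
  x0 <- if (is.null(p$x0)) w[1] else p$x0
  out <- kalman_scalar_cpp(w, p$A, p$H, p$Q, p$R, x0, p$P0)
  structure(out$x, P = out$P)
}

# mean removal
demean <- function(w) w - mean(w)

# baseline removal: per-window least-squares fit of a low-order polynomial.
# Over a 2.56 s window, maternal breathing (~0.3 Hz, under one cycle) is a
# smooth trend that a degree-4 polynomial absorbs almost completely, while
# localized 2-10 Hz movement transients are barely affected.
detrend_poly <- function(w, degree = 4L) {
  w <- as.numeric(w)
  n <- length(w)
  x <- seq(-1, 1, length.out = n)
  B <- stats::poly(x, degree = degree)
  wc <- w - mean(w)
  as.numeric(wc - B %*% crossprod(B, wc))
}

# mean-removed, unit-l2-norm copy of a window: the normalization convention
# shared by dictionary training and both classifiers (the gate has already
# consumed the amplitude information, so matching is shape-only).
normalize_window <- function(w) {
  w <- demean(as.numeric(w))
  n <- sqrt(sum(w^2))
  if (n < 1e-12) stop("degenerate input: window has (near-)zero norm after mean removal")
  w / n
}

#' Preprocess segmented windows for gating and classification
#'
#' Applies, per axis and per window, DC/baseline correction followed by
#' Kalman smoothing. `dc_method = "detrend"` (default) removes a per-window
#' degree-4 polynomial baseline, which cancels the DC offset and absorbs
#' the sub-1 Hz maternal-breathing trend while preserving the amplitude of
#' localized movement transients; `"demean"` subtracts only the window
#' mean; `"diff"` uses first differences ([remove_dc()]). Unless given, the
#' measurement-noise variance `R` is estimated per axis as the variance of
#' the recording's first (assumed quiet baseline) window after the same
#' DC correction.
#'
#' @param seg segmentation from [segment_windows()].
#' @param Q process-noise variance in g^2 (default 5e-5).
#' @param R optional measurement-noise variance; scalar or length-6 vector.
#' @param dc_method `"detrend"`, `"demean"` or `"diff"`.
#' @return `seg` with `windows` replaced by the preprocessed array and the
#'   per-axis `R` estimates attached as `kalman_R`.
#' @export
preprocess_windows <- function(seg, Q = 5e-5, R = NULL,
                               dc_method = c("detrend", "demean", "diff")) {
  dc_method <- match.arg(dc_method)
  arr <- seg$windows
  n_axes <- dim(arr)[3]
  dc_fun <- switch(dc_method, detrend = detrend_poly, demean = demean,
                   diff = remove_dc)
  if (is.null(R)) {
    R <- vapply(seq_len(n_axes),
                function(a) max(stats::var(dc_fun(arr[, 1, a])), 1e-12),
                numeric(1))
  } else {
    R <- rep_len(R, n_axes)
    if (any(R <= 0)) stop("parameter error: R must be > 0")
  }
  for (a in seq_len(n_axes)) {
    p <- kalman_params(Q = Q, R = R[a])
    for (k in seq_len(dim(arr)[2])) {
      w <- dc_fun(arr[, k, a])
      arr[, k, a] <- as.numeric(kalman_filter(w, p))
    }
  }
  seg$windows <- arr
  seg$kalman_R <- R
  seg$dc_method <- dc_method
  seg
}
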