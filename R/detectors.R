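#' LMS adaptive-filter parameters
#'
#' @param M number of FIR taps `w_0 ... w_{M-1}` (>= 1).
#' @param mu step size of the stochastic-gradient update (> 0); defaults
#'   assume unit-norm signals.
#' @param max_epochs maximum full passes over the window.
#' @param tol convergence tolerance on the change in per-pass MSE.
#' @return an object of class `lms_params`.
#' @export
lms_params <- function(M = 8L, mu = 0.05, max_epochs = 100L, tol = 1e-8) {
  M <- as.integer(M)
  if (M < 1L) stop("parameter error: M must be >= 1")
  if (mu <= 0) stop("parameter error: mu must be > 0")
  structure(list(M = M, mu = mu, max_epochs = as.integer(max_epochs), tol = tol),
            class = "lms_params")
}

#' LMS adaptive-filter fit of a reference signal to a desired window
#'
#' Runs the least-mean-squares recursion: the FIR output is
#' `rhat(n) = sum_m w_m(n) r(n - m)` (samples before index 0 are zero), the
#' instantaneous error is `e(n) = d(n) - rhat(n)`, and each tap is updated
#' as `w_m(n+1) = w_m(n) + 2 mu e(n) r(n - m)`. Whole passes (epochs) over
#' the window are repeated, carrying the weights over, until the per-pass
#' mean squared error changes by less than `tol` or `max_epochs` is reached.
#'
#' @param d desired signal (the test window), numeric vector.
#' @param r reference signal (a dictionary atom), same length as `d`.
#' @param p [lms_params()] object.
#' @param w0 optional initial tap weights of length `M` (default all zero).
#' @return final-pass mean of `e(n)^2`, with attributes `weights` (final
#'   taps) and `epochs` (passes run).
#' @export
lms_fit <- function(d, r, p = lms_params(), w0 = NULL) {
  stopifnot(inherits(p, "lms_params"))
  d <- as.numeric(d); r <- as.numeric(r)
  if (length(d) != length(r))
    stop("configuration error: desired and reference signals must have equal length")
  if (is.null(w0)) w0 <- numeric(p$M)
  if (length(w0) != p$M) stop("parameter error: w0 must have length M")
  out <- lms_fit_cpp(d, r, p$M, p$mu, p$max_epochs, p$tol, w0)
  if (out$diverged)
    stop("instability error: LMS mean squared error exceeded 1e6; ",
         "try a smaller step size mu")
  structure(out$mse, weights = out$weights, epochs = out$epochs)
}

new_axis_decision <- function(label, err_fm, err_nonfm, method,
                              axis_index = NA_integer_) {
  structure(list(axis_index = axis_index, label = label,
                 err_fm = err_fm, err_nonfm = err_nonfm, method = method),
            class = "axis_decision")
}

# label per the decision contract: FM iff err_fm < err_nonfm, ties -> NON_FM
decide_label <- function(err_fm, err_nonfm) {
  if (err_fm < err_nonfm) "FM" else "NON_FM"
}

check_dict_pair <- function(D1, D2, y) {
  m1 <- nrow(dict_matrix(D1)); m2 <- nrow(dict_matrix(D2))
  if (m1 != m2)
    stop("configuration error: dictionaries have mismatched atom length (",
         m1, " vs ", m2, ")")
  if (length(y) != m1)
    stop("configuration error: window length ", length(y),
         " does not match dictionary atom length ", m1)
}

#' Dual-dictionary OMP residual classifier for one axis window
#'
#' Codes the (normalized) window independently against the FM dictionary
#' `D1` and the non-FM dictionary `D2` with [omp_code()] at sparsity `T0`;
#' the two residual norms are the class reconstruction errors, and the class
#' with the lower error labels the window (ties go to non-FM).
#'
#' @param y candidate window (gate-passed), numeric vector.
#' @param D1 FM feature dictionary ([ksvd()] object or matrix).
#' @param D2 non-FM feature dictionary.
#' @param T0 sparsity (default 3, the operating optimum).
#' @param axis_index optional ordinal carried through.
#' @return an object of class `axis_decision`: `label` (`"FM"`/`"NON_FM"`),
#'   `err_fm`, `err_nonfm`, `method = "OMP"`.
#' @export
omp_classify <- function(y, D1, D2, T0 = 3L, axis_index = NA_integer_) {
  check_dict_pair(D1, D2, y)
  yn <- normalize_window(y)
  err_fm <- omp_code(D1, yn, T0)$residual_norm
  err_nonfm <- omp_code(D2, yn, T0)$residual_norm
  new_axis_decision(decide_label(err_fm, err_nonfm), err_fm, err_nonfm,
                    "OMP", axis_index)
}

#' Dual-dictionary LMS adaptive-filter classifier for one axis window
#'
#' Adaptively matches the (normalized) window against every atom of both
#' dictionaries: for each atom, [lms_fit()] is run with the atom as the
#' filter's reference input and the window as the desired signal; the class
#' errors are the minima of the final MSE over each dictionary's atoms, and
#' the smaller one labels the window (ties go to non-FM).
#'
#' @inheritParams omp_classify
#' @param p [lms_params()] object.
#' @return an object of class `axis_decision` with `method = "LMS"`.
#' @export
lms_classify <- function(y, D1, D2, p = lms_params(), axis_index = NA_integer_) {
  stopifnot(inherits(p, "lms_params"))
  check_dict_pair(D1, D2, y)
  yn <- normalize_window(y)
  scan <- function(D) {
    res <- lms_dict_cpp(yn, dict_matrix(D), p$M, p$mu, p$max_epochs, p$tol)
    if (res$diverged)
      stop("instability error: LMS mean squared error exceeded 1e6; ",
           "try a smaller step size mu")
    min(res$mse)
  }
  err_fm <- scan(D1)
  err_nonfm <- scan(D2)
  new_axis_decision(decide_label(err_fm, err_nonfm), err_fm, err_nonfm,
                    "LMS", axis_index)
}

#' @export
print.axis_decision <- function(x, ...) {
  cat(sprintf("axis decision [%s]: %s (err_fm = %.4g, err_nonfm = %.4g)\n",
              x$method, x$label, x$err_fm, x$err_nonfm))
  invisible(x)
}
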