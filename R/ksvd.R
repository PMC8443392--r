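#' Orthogonal matching pursuit sparse coding
#'
#' Greedy sparse approximation of a signal over a dictionary: at each of at
#' most `T0` steps the atom with the largest absolute correlation with the
#' current residual is added to the support, and all coefficients on the
#' accumulated support are re-fitted by least squares, leaving the residual
#' orthogonal to the span of the selected atoms. Selection stops early when
#' the residual is numerically zero.
#'
#' @param D dictionary: `m x n` numeric matrix of unit-norm atoms, or a
#'   fitted [ksvd()] object.
#' @param y signal of length `m` (callers normalize per the package's
#'   mean-removed unit-norm convention where relevant).
#' @param T0 sparsity limit: maximum number of nonzero coefficients (>= 1).
#' @return an object of class `sparse_code`: list with `coefficients`
#'   (length-`n`, exact zeros off the support), `support` (selected atom
#'   indices in selection order), `residual_norm`, `sparsity_limit`.
#' @export
omp_code <- function(D, y, T0 = 3L) {
  D <- dict_matrix(D)
  y <- as.numeric(y)
  if (length(y) != nrow(D))
    stop("configuration error: signal length ", length(y),
         " does not match atom length ", nrow(D))
  n <- ncol(D)
  T0 <- as.integer(T0)
  if (T0 < 1L) stop("parameter error: T0 must be >= 1")
  if (T0 > n) stop("parameter error: T0 (", T0, ") exceeds atom count (", n, ")")
  if (sqrt(sum(y^2)) < 1e-12)
    stop("degenerate input: cannot code a (near-)zero-norm signal")
  support <- integer(0)
  beta <- numeric(0)
  r <- y
  for (step in seq_len(T0)) {
    if (sqrt(sum(r^2)) < 1e-12) break
    corr <- abs(crossprod(D, r))
    corr[support] <- -Inf
    j <- which.max(corr)
    if (!is.finite(corr[j]) || corr[j] < 1e-12) break
    support <- c(support, j)
    A <- D[, support, drop = FALSE]
    beta <- qr.coef(qr(A), y)
    r <- y - A %*% beta
  }
  x <- numeric(n)
  x[support] <- beta
  structure(list(coefficients = x, support = support,
                 residual_norm = sqrt(sum(r^2)), sparsity_limit = T0),
            class = "sparse_code")
}

#' Residual norm of a sparse approximation
#'
#' @param D dictionary matrix or [ksvd()] object.
#' @param x a `sparse_code` or a plain coefficient vector of length `n`.
#' @param y the coded signal.
#' @return `||y - D x||_2`.
#' @export
reconstruction_error <- function(D, x, y) {
  D <- dict_matrix(D)
  if (inherits(x, "sparse_code")) x <- x$coefficients
  if (length(x) != ncol(D)) stop("configuration error: coefficient length mismatch")
  if (length(y) != nrow(D)) stop("configuration error: signal length mismatch")
  sqrt(sum((as.numeric(y) - as.numeric(D %*% x))^2))
}

dict_matrix <- function(D) {
  if (inherits(D, "ksvd")) D$D
  else as.matrix(D)
}

#' K-SVD dictionary learning
#'
#' Learns a feature dictionary for one signal class by alternating (a)
#' sparse coding of every training column with [omp_code()] under an l0
#' constraint `T0` and (b) sequential atom updates: for atom `j`, the
#' residual matrix of the columns using `j` (with atom `j`'s own
#' contribution restored) is decomposed by SVD, and the atom and its
#' coefficient row are replaced by the leading left/right singular vectors
#' scaled by the leading singular value. Within each iteration the update
#' sweep never increases the objective `||Y - D X||_F` relative to the
#' coding stage (greedy re-coding between iterations carries no such
#' guarantee, as usual for K-SVD). Atoms remain unit-norm
#' throughout; an atom used by no column is replaced by the currently
#' worst-represented training column, normalized.
#'
#' @param Y training matrix, `m x L` (`L >= n_atoms` columns, one training
#'   window per column, already normalized by the caller's convention), or a
#'   training-set object from [make_training_sets()].
#' @param n_atoms number of dictionary atoms (default 256; equal to `m` for
#'   a complete dictionary).
#' @param T0 sparsity limit used for the coding stage (default 3).
#' @param n_iter maximum alternations (default 30); `n_iter = 0` returns the
#'   seeded initialization (random training columns, normalized) unchanged.
#' @param seed integer seed controlling initialization (and nothing else).
#' @param class_label class tag, `"FM"` or `"NON_FM"` (or any string).
#' @param tol_rel early stop when the relative objective improvement over
#'   one iteration falls below this (default 1e-6).
#' @return an object of class `ksvd`: list with `D` (the `m x n_atoms`
#'   dictionary), `class_label`, `m`, `n_atoms`, `T0`, `objective`
#'   (per-iteration `||Y - DX||_F` after the update sweep; the value after
#'   the coding stage is in `objective_coding`)
#'   (per-iteration `||Y - DX||_F`), `n_iter_run`, `seed`, `converged`.
#' @export
ksvd <- function(Y, n_atoms = 256L, T0 = 3L, n_iter = 30L, seed = 1L,
                 class_label = "FM", tol_rel = 1e-6) {
  if (inherits(Y, "fm_training_set")) {
    if (missing(class_label)) class_label <- Y$class_label
    Y <- Y$Y
  }
  Y <- as.matrix(Y)
  if (anyNA(Y) || any(!is.finite(Y))) stop("data error: non-finite values in Y")
  m <- nrow(Y); L <- ncol(Y)
  n_atoms <- as.integer(n_atoms)
  if (L < n_atoms)
    stop("need at least n_atoms = ", n_atoms, " training columns, got ", L)
  cn <- sqrt(colSums(Y^2))
  if (any(cn < 1e-12)) stop("data error: zero-norm training column(s)")

  D <- with_seed(seed, {
    pick <- sample.int(L, n_atoms)
    Di <- Y[, pick, drop = FALSE]
    sweep(Di, 2L, sqrt(colSums(Di^2)), "/")
  })

  objective <- numeric(0)
  objective_coding <- numeric(0)
  X <- NULL
  it_run <- 0L
  converged <- FALSE
  for (it in seq_len(max(0L, as.integer(n_iter)))) {
    # sparse coding stage
    X <- matrix(0, n_atoms, L)
    for (l in seq_len(L)) {
      sc <- omp_code(D, Y[, l], T0)
      X[, l] <- sc$coefficients
    }
    # dictionary update stage
    Resid <- Y - D %*% X
    objective_coding <- c(objective_coding, sqrt(sum(Resid^2)))
    for (j in seq_len(n_atoms)) {
      omega <- which(X[j, ] != 0)
      if (length(omega) == 0L) {
        # dead atom: replace with the worst-represented column
        errs <- colSums(Resid^2)
        worst <- which.max(errs)
        newatom <- Y[, worst] / sqrt(sum(Y[, worst]^2))
        D[, j] <- newatom
        next
      }
      Ej <- Resid[, omega, drop = FALSE] +
        D[, j, drop = FALSE] %*% X[j, omega, drop = FALSE]
      sv <- svd(Ej, nu = 1L, nv = 1L)
      D[, j] <- sv$u[, 1]
      X[j, omega] <- sv$d[1] * sv$v[, 1]
      Resid[, omega] <- Ej - D[, j, drop = FALSE] %*% X[j, omega, drop = FALSE]
    }
    obj <- sqrt(sum((Y - D %*% X)^2))
    objective <- c(objective, obj)
    it_run <- it
    if (it > 1L) {
      prev <- objective[it - 1L]
      if (prev < 1e-12 || (prev - obj) / prev < tol_rel) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(D = D, class_label = class_label, m = m, n_atoms = n_atoms,
                 T0 = as.integer(T0), objective = objective,
                 objective_coding = objective_coding,
                 n_iter_run = it_run, seed = seed, converged = converged),
            class = "ksvd")
}

#' @export
print.ksvd <- function(x, ...) {
  cat(sprintf("K-SVD feature dictionary (%s): %d x %d, T0 = %d\n",
              x$class_label, x$m, x$n_atoms, x$T0))
  if (length(x$objective))
    cat(sprintf("  %d iteration(s), final ||Y - DX||_F = %.4g%s\n",
                x$n_iter_run, tail(x$objective, 1),
                if (x$converged) " (converged)" else ""))
  else cat("  untrained initialization (n_iter = 0)\n")
  invisible(x)
}

#' @export
summary.ksvd <- function(object, ...) {
  mutual <- abs(crossprod(object$D))
  diag(mutual) <- 0
  out <- list(class_label = object$class_label, m = object$m,
              n_atoms = object$n_atoms, T0 = object$T0,
              objective = object$objective,
              max_coherence = max(mutual),
              atom_norm_range = range(sqrt(colSums(object$D^2))))
  class(out) <- "summary.ksvd"
  out
}

#' @export
print.summary.ksvd <- function(x, ...) {
  cat(sprintf("K-SVD dictionary (%s), %d x %d\n", x$class_label, x$m, x$n_atoms))
  cat(sprintf("  atom norms in [%.6f, %.6f]; max mutual coherence %.3f\n",
              x$atom_norm_range[1], x$atom_norm_range[2], x$max_coherence))
  if (length(x$objective))
    cat(sprintf("  objective: %.4g -> %.4g over %d iteration(s)\n",
                x$objective[1], tail(x$objective, 1), length(x$objective)))
  invisible(x)
}

#' @export
coef.ksvd <- function(object, ...) object$D

#' Sparse-code new windows against a fitted dictionary
#'
#' @param object fitted [ksvd()] dictionary.
#' @param newdata a numeric vector (one window) or a matrix of windows in
#'   columns, already normalized by the caller's convention.
#' @param T0 sparsity limit (default: the training `T0`).
#' @param type `"code"` for sparse codes, `"reconstruction"` for `D x`,
#'   `"error"` for residual norms.
#' @param ... unused.
#' @return a `sparse_code` (vector input) or list of them; for
#'   `"reconstruction"` a vector/matrix; for `"error"` a numeric vector.
#' @export
predict.ksvd <- function(object, newdata, T0 = object$T0,
                         type = c("code", "reconstruction", "error"), ...) {
  type <- match.arg(type)
  single <- is.null(dim(newdata))
  M <- if (single) matrix(as.numeric(newdata), ncol = 1L) else as.matrix(newdata)
  codes <- lapply(seq_len(ncol(M)), function(l) omp_code(object, M[, l], T0))
  out <- switch(type,
    code = codes,
    reconstruction = vapply(codes, function(sc)
      as.numeric(object$D %*% sc$coefficients), numeric(object$m)),
    error = vapply(codes, function(sc) sc$residual_norm, numeric(1)))
  if (single && type == "code") out[[1]]
  else if (single && type == "reconstruction") as.numeric(out)
  else out
}

#' Plot a grid of dictionary atoms
#'
#' Qualitative atom-grid image of a learned dictionary: each panel is one
#' atom waveform.
#'
#' @param x fitted [ksvd()] object.
#' @param n_show number of atoms to draw (default 16).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ksvd <- function(x, n_show = 16L, ...) {
  n_show <- min(n_show, x$n_atoms)
  side <- ceiling(sqrt(n_show))
  old <- par(mfrow = c(side, side), mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(par(old))
  for (j in seq_len(n_show))
    graphics::plot(x$D[, j], type = "l", axes = FALSE, xlab = "", ylab = "", ...)
  invisible(x)
}

#' Save / load a feature dictionary as plain text
#'
#' Portable text container: a header of `key: value` metadata lines
#' (class label, dimensions, training sparsity, sampling context, seed)
#' followed by the dictionary matrix, one row per line at full double
#' precision. The round trip is lossless to well below 1e-12.
#'
#' @param obj fitted [ksvd()] object.
#' @param path file path.
#' @param sample_rate,window_seconds sampling context stored alongside.
#' @return `path` invisibly (write); a `ksvd` object (read).
#' @export
write_dictionary <- function(obj, path, sample_rate = 100, window_seconds = 2.56) {
  stopifnot(inherits(obj, "ksvd"))
  hdr <- c("# fmdetect feature dictionary v1",
           paste0("class_label: ", obj$class_label),
           paste0("m: ", obj$m),
           paste0("n_atoms: ", obj$n_atoms),
           paste0("T0: ", obj$T0),
           paste0("sample_rate: ", format(sample_rate)),
           paste0("window_seconds: ", format(window_seconds)),
           paste0("seed: ", format(obj$seed)),
           "matrix:")
  rows <- apply(obj$D, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sep <- which(lines == "matrix:")[1]
  if (is.na(sep)) stop("format error: not a dictionary container: ", path)
  meta <- lines[2:(sep - 1L)]
  kv <- do.call(rbind, strsplit(meta, ": ", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  D <- do.call(rbind, lapply(lines[(sep + 1L):length(lines)],
                             function(l) as.numeric(strsplit(l, " ", fixed = TRUE)[[1]])))
  if (nrow(D) != as.integer(meta["m"]) || ncol(D) != as.integer(meta["n_atoms"]))
    stop("format error: dictionary dimensions do not match header")
  structure(list(D = D, class_label = unname(meta["class_label"]),
                 m = nrow(D), n_atoms = ncol(D),
                 T0 = as.integer(meta["T0"]), objective = numeric(0),
                 n_iter_run = NA_integer_,
                 seed = suppressWarnings(as.integer(meta["seed"])),
                 converged = NA),
            class = "ksvd")
}
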