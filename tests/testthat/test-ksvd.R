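test_that("omp_code recovers exact and orthogonal sparse combinations", {
  D <- random_orthonormal_dict(32, 16, seed = 3)
  sc <- omp_code(D, D[, 7], T0 = 3)
  expect_equal(sc$support[1], 7L)
  expect_equal(sc$coefficients[7], 1.0, tolerance = 1e-12)
  expect_equal(sc$residual_norm, 0, tolerance = 1e-10)
  expect_equal(sum(sc$coefficients != 0), 1L)

  y <- 0.6 * D[, 2] + 0.8 * D[, 11]
  sc2 <- omp_code(D, y, T0 = 2)
  expect_equal(sort(sc2$support), c(2L, 11L))
  expect_equal(sc2$coefficients[c(2, 11)], c(0.6, 0.8), tolerance = 1e-12)
  expect_equal(sc2$residual_norm, 0, tolerance = 1e-10)
})

test_that("omp_code residual equals the least-squares fit on its support", {
  for (s in 1:200) {
    D <- random_orthonormal_dict(24, 24, seed = s)
    y <- with_seed(5000 + s, rnorm(24))
    sc <- omp_code(D, y, T0 = 3)
    # independent oracle: explicit least squares on the selected atoms
    A <- D[, sc$support, drop = FALSE]
    beta <- solve(crossprod(A), crossprod(A, y))
    oracle <- sqrt(sum((y - A %*% beta)^2))
    expect_equal(sc$residual_norm, oracle, tolerance = 1e-8)
    # residual is orthogonal to the span of the selected atoms
    r <- y - A %*% sc$coefficients[sc$support]
    expect_lt(max(abs(crossprod(A, r))), 1e-8)
  }
})

test_that("omp_code residual norm is non-increasing in the sparsity limit", {
  D <- random_orthonormal_dict(40, 40, seed = 8)
  y <- with_seed(99, rnorm(40))
  res <- vapply(1:10, function(t0) omp_code(D, y, t0)$residual_norm, numeric(1))
  expect_true(all(diff(res) <= 1e-10))
})

test_that("omp_code rejects degenerate inputs", {
  D <- random_orthonormal_dict(16, 8, seed = 1)
  expect_error(omp_code(D, rep(0, 16), 2), "zero-norm")
  expect_error(omp_code(D, rnorm(16), 9), "exceeds atom count")
  expect_error(omp_code(D, rnorm(16), 0), "T0 must be >= 1")
  expect_error(omp_code(D, rnorm(15), 2), "does not match atom length")
})

test_that("reconstruction_error equals the recomputed residual norm", {
  D <- random_orthonormal_dict(20, 12, seed = 4)
  y <- with_seed(7, rnorm(20))
  sc <- omp_code(D, y, 4)
  expect_equal(reconstruction_error(D, sc, y), sc$residual_norm,
               tolerance = 1e-10)
  expect_equal(reconstruction_error(D, rep(0, 12), y), sqrt(sum(y^2)))
  x <- with_seed(8, rnorm(12))
  expect_equal(reconstruction_error(D, x, y),
               sqrt(sum((y - as.numeric(D %*% x))^2)))
})

test_that("ksvd drives the objective to zero when a perfect dictionary exists", {
  # columns are 8 distinct unit vectors, each repeated 6 times
  m <- 8
  Y <- diag(m)[, rep(seq_len(m), each = 6)]
  fit <- ksvd(Y, n_atoms = m, T0 = 1, n_iter = 10, seed = 2)
  expect_lt(tail(fit$objective, 1), 1e-6)
})

test_that("ksvd with n_iter = 0 returns the seeded initialization unchanged", {
  Y <- with_seed(31, matrix(rnorm(16 * 40), 16, 40))
  fit <- ksvd(Y, n_atoms = 10, T0 = 2, n_iter = 0, seed = 5)
  expect_length(fit$objective, 0L)
  # every atom is a normalized training column
  Yn <- sweep(Y, 2, sqrt(colSums(Y^2)), "/")
  match_ok <- apply(fit$D, 2, function(a)
    any(abs(crossprod(Yn, a)) > 1 - 1e-10))
  expect_true(all(match_ok))
})

test_that("ksvd objective is non-increasing and atoms stay unit-norm", {
  for (s in 1:3) {
    D0 <- with_seed(s + 900, {
      D <- matrix(rnorm(16 * 20), 16, 20)
      sweep(D, 2, sqrt(colSums(D^2)), "/")
    })
    X0 <- with_seed(s, {
      X <- matrix(0, 20, 120)
      for (l in 1:120) X[sample(20, 3), l] <- rnorm(3)
      X
    })
    Y <- D0 %*% X0 + with_seed(100 + s, matrix(rnorm(16 * 120, sd = 0.01), 16, 120))
    fit <- ksvd(Y, n_atoms = 20, T0 = 3, n_iter = 15, seed = s, tol_rel = 0)
    # every update sweep contracts the objective at fixed supports
    expect_true(all(fit$objective <= fit$objective_coding + 1e-8))
    # and training improves on the initial fit overall
    expect_lt(tail(fit$objective, 1), fit$objective_coding[1])
    expect_equal(sqrt(colSums(fit$D^2)), rep(1, 20), tolerance = 1e-10)
  }
})

test_that("ksvd recovers a planted dictionary", {
  m <- 20; n <- 24; L <- 480
  Dtrue <- with_seed(77, {
    D <- matrix(rnorm(m * n), m, n)
    sweep(D, 2, sqrt(colSums(D^2)), "/")
  })
  Y <- with_seed(78, {
    X <- matrix(0, n, L)
    for (l in seq_len(L)) X[sample(n, 3), l] <- rnorm(3)
    Dtrue %*% X + matrix(rnorm(m * L, sd = 0.01), m, L)
  })
  fit <- ksvd(Y, n_atoms = n, T0 = 3, n_iter = 30, seed = 79)
  # best-matched, sign-invariant atom correlation
  corr <- abs(crossprod(Dtrue, fit$D))
  recovery <- apply(corr, 1, max)
  expect_gte(mean(recovery), 0.9)
})

test_that("ksvd is deterministic for a fixed seed", {
  Y <- with_seed(55, matrix(rnorm(16 * 60), 16, 60))
  f1 <- ksvd(Y, n_atoms = 12, T0 = 2, n_iter = 5, seed = 9)
  f2 <- ksvd(Y, n_atoms = 12, T0 = 2, n_iter = 5, seed = 9)
  expect_identical(f1$D, f2$D)
  f3 <- ksvd(Y, n_atoms = 12, T0 = 2, n_iter = 5, seed = 10)
  expect_false(identical(f1$D, f3$D))
})

test_that("ksvd validates its training matrix", {
  expect_error(ksvd(matrix(NA_real_, 8, 10), n_atoms = 4), "non-finite")
  expect_error(ksvd(matrix(rnorm(80), 8, 10), n_atoms = 16),
               "at least n_atoms")
  Y <- matrix(rnorm(80), 8, 10); Y[, 3] <- 0
  expect_error(ksvd(Y, n_atoms = 4), "zero-norm")
})

test_that("dictionary text container round-trips losslessly", {
  Y <- with_seed(91, matrix(rnorm(16 * 40), 16, 40))
  fit <- ksvd(Y, n_atoms = 10, T0 = 2, n_iter = 3, seed = 6,
              class_label = "NON_FM")
  path <- tempfile(fileext = ".txt")
  write_dictionary(fit, path)
  back <- read_dictionary(path)
  expect_lt(max(abs(back$D - fit$D)), 1e-12)
  expect_equal(back$class_label, "NON_FM")
  expect_equal(back$T0, 2L)
  expect_equal(back$m, 16L)
  expect_equal(back$n_atoms, 10L)
})

test_that("ksvd methods expose the fit", {
  Y <- with_seed(13, matrix(rnorm(16 * 30), 16, 30))
  fit <- ksvd(Y, n_atoms = 8, T0 = 2, n_iter = 3, seed = 1)
  expect_identical(coef(fit), fit$D)
  expect_output(print(fit), "K-SVD feature dictionary")
  expect_output(print(summary(fit)), "atom norms")
  sc <- predict(fit, Y[, 4])
  expect_s3_class(sc, "sparse_code")
  errs <- predict(fit, Y[, 1:5], type = "error")
  expect_length(errs, 5L)
  expect_true(all(errs >= 0))
  rec <- predict(fit, Y[, 4], type = "reconstruction")
  expect_equal(rec, as.numeric(fit$D %*% sc$coefficients))
})
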