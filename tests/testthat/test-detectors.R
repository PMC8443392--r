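# two small synthetic dictionaries whose atoms are mutually distinct:
# D1 holds localized oscillatory packets, D2 holds smooth arcs
toy_dict_pair <- function(m = 64) {
  t <- seq(0, 1, length.out = m)
  mk <- function(waves) {
    D <- vapply(waves, function(w) {
      w <- w - mean(w)
      w / sqrt(sum(w^2))
    }, numeric(m))
    D
  }
  D1 <- mk(lapply(seq(2, 9), function(f)
    exp(-(t - 0.5)^2 / 0.02) * sin(2 * pi * f * t)))
  D2 <- mk(lapply(seq(0.3, 1, length.out = 8), function(f)
    sin(pi * f * t)))
  list(D1 = D1, D2 = D2)
}

test_that("omp_classify labels exact atoms by their own dictionary", {
  d <- toy_dict_pair()
  out1 <- omp_classify(d$D1[, 3], d$D1, d$D2, T0 = 2)
  expect_equal(out1$label, "FM")
  expect_equal(out1$err_fm, 0, tolerance = 1e-8)
  out2 <- omp_classify(d$D2[, 5], d$D1, d$D2, T0 = 2)
  expect_equal(out2$label, "NON_FM")
  expect_equal(out2$err_nonfm, 0, tolerance = 1e-8)
})

test_that("omp_classify is invariant to positive rescaling", {
  d <- toy_dict_pair()
  for (s in 1:20) {
    y <- with_seed(300 + s, rnorm(64))
    a <- omp_classify(y, d$D1, d$D2)
    b <- omp_classify(1000 * y, d$D1, d$D2)
    cc <- omp_classify(1e-3 * y, d$D1, d$D2)
    expect_identical(a$label, b$label)
    expect_identical(a$label, cc$label)
    expect_equal(a$err_fm, b$err_fm, tolerance = 1e-9)
    expect_true(is.finite(a$err_fm) && a$err_fm >= 0)
    expect_true(is.finite(a$err_nonfm) && a$err_nonfm >= 0)
  }
})

test_that("swapping the dictionaries inverts every non-tied label", {
  d <- toy_dict_pair()
  for (s in 1:20) {
    y <- with_seed(400 + s, rnorm(64))
    a <- omp_classify(y, d$D1, d$D2)
    b <- omp_classify(y, d$D2, d$D1)
    if (abs(a$err_fm - a$err_nonfm) > 1e-12)
      expect_false(identical(a$label, b$label))
  }
})

test_that("classifier rejects mismatched dictionary dimensions", {
  d <- toy_dict_pair()
  expect_error(omp_classify(rnorm(64), d$D1, d$D2[1:32, ]), "mismatched")
  expect_error(omp_classify(rnorm(32), d$D1, d$D2), "window length")
})

test_that("lms_fit is exact for an identity filter and a matched signal", {
  r <- with_seed(17, rnorm(128))
  mse <- lms_fit(r, r, lms_params(M = 4, mu = 0.01, max_epochs = 1),
                 w0 = c(1, 0, 0, 0))
  expect_equal(as.numeric(mse), 0)
  expect_equal(attr(mse, "weights"), c(1, 0, 0, 0))
})

test_that("lms_fit is bounded below by the Wiener solution", {
  for (s in 1:30) {
    n <- 128; M <- 6
    r <- with_seed(600 + s, rnorm(n))
    d <- with_seed(700 + s, rnorm(n))
    mse <- as.numeric(lms_fit(d, r, lms_params(M = M, mu = 0.02,
                                               max_epochs = 200, tol = 1e-12)))
    # normal-equation oracle on the same tapped-delay matrix
    Rm <- sapply(0:(M - 1), function(m) c(numeric(m), r)[seq_len(n)])
    beta <- qr.solve(Rm, d)
    wiener <- mean((d - Rm %*% beta)^2)
    expect_gte(mse + 1e-10, wiener)
  }
})

test_that("lms_fit identifies a unit-delay channel", {
  r <- with_seed(41, rnorm(256))
  d <- c(0, r[-256])
  mse <- lms_fit(d, r, lms_params(M = 4, mu = 0.05, max_epochs = 300,
                                  tol = 1e-12))
  w <- attr(mse, "weights")
  expect_equal(which.max(abs(w)), 2L)  # tap index 1 (0-based)
  expect_gt(abs(w[2]), 0.9)
  expect_lt(as.numeric(mse), 0.01)
})

test_that("lms_fit raises an instability error for oversized steps", {
  r <- with_seed(43, rnorm(256))
  d <- with_seed(44, rnorm(256))
  expect_error(lms_fit(d, r, lms_params(M = 8, mu = 50)), "instability")
  expect_error(lms_fit(d, r[1:100], lms_params()), "equal length")
})

test_that("lms_classify matches atoms and breaks ties toward non-FM", {
  d <- toy_dict_pair()
  p <- lms_params(M = 4, mu = 0.05, max_epochs = 50)
  out <- lms_classify(d$D1[, 2], d$D1, d$D2, p)
  expect_equal(out$label, "FM")
  expect_lt(out$err_fm, 1e-4)
  # identical dictionaries produce exactly equal errors -> NON_FM by tie rule
  tie <- lms_classify(with_seed(9, rnorm(64)), d$D1, d$D1, p)
  expect_identical(tie$err_fm, tie$err_nonfm)
  expect_equal(tie$label, "NON_FM")
})

test_that("LMS detector accuracy is comparable to the OMP detector", {
  dicts <- shared_dicts()
  ho <- fixture("holdout_lms", make_training_sets(synth_config(seed = 555), 30L))
  p <- lms_params()
  lms_lab <- function(Y) vapply(seq_len(ncol(Y)), function(l)
    lms_classify(Y[, l], dicts$D1, dicts$D2, p)$label, character(1))
  acc_lms <- (mean(lms_lab(ho$fm$Y) == "FM") +
                mean(lms_lab(ho$nonfm$Y) == "NON_FM")) / 2
  acc_omp <- (mean(classify_columns(ho$fm$Y, dicts$D1, dicts$D2) == "FM") +
                mean(classify_columns(ho$nonfm$Y, dicts$D1, dicts$D2) == "NON_FM")) / 2
  expect_gte(acc_lms, acc_omp - 0.10)
})
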