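tspec5 <- spline_spec("quadratic_bspline", c(8, 12, 16), c(0, 30))  # dim 5

test_that("zero-lag constant cross-basis degenerates to the temperature basis", {
  spec <- crossbasis_spec(tspec5, lag_spline = "constant", max_lag = 0L)
  x <- seq(2, 28, length.out = 40)
  cb <- build_crossbasis(x, spec)
  expect_equal(unname(cb)[, ], unname(eval_spline(x, tspec5))[, ],
               ignore_attr = TRUE)
})

test_that("a constant temperature series gives identical cross-basis rows", {
  lag <- spline_spec("natural_cubic", c(1.5), c(0, 5), intercept = TRUE)
  spec <- crossbasis_spec(tspec5, lag_spline = lag, max_lag = 5L)
  cb <- build_crossbasis(rep(17, 30), spec)
  expect_lt(max(abs(sweep(cb, 2, cb[1, ]))), 1e-12)
})

test_that("cross-basis matches the literal tensor-product triple loop", {
  set.seed(5)
  temps <- stats::runif(50, 1, 29)
  lag <- spline_spec("natural_cubic", numeric(), c(0, 3), intercept = TRUE) # v_l = 2
  spec <- crossbasis_spec(tspec5, lag_spline = lag, max_lag = 3L)
  cb <- build_crossbasis(temps, spec)
  C <- lag_basis_matrix(spec)
  expect_equal(dim(cb), c(47L, 10L))
  expect_equal(unname(cb)[, ], crossbasis_oracle(temps, tspec5, C, 3L),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the moving-average cross-basis is the basis of the window mean", {
  spec <- crossbasis_spec(tspec5, lag_spline = "ma", max_lag = 2L)
  set.seed(6)
  temps <- stats::runif(20, 5, 25)
  cb <- build_crossbasis(temps, spec)
  ma <- vapply(3:20, function(t) mean(temps[(t - 2):t]), 0)
  expect_equal(unname(cb)[, ], unname(eval_spline(ma, tspec5))[, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("series shorter than the lag window is an error", {
  lag <- spline_spec("natural_cubic", numeric(), c(0, 5), intercept = TRUE)
  spec <- crossbasis_spec(tspec5, lag_spline = lag, max_lag = 5L)
  expect_error(build_crossbasis(rep(10, 5), spec), "at least L \\+ 1")
})

test_that("reduction is the identity when there is nothing to cumulate", {
  spec <- crossbasis_spec(tspec5, lag_spline = "constant", max_lag = 0L)
  eta <- c(0.1, -0.2, 0.3, 0.05, -0.1)
  V <- diag(0.01, 5)
  rf <- reduce_coefficients(eta, V, spec, temps = seq(0, 30, by = 0.5))
  expect_equal(rf$beta, eta)
  expect_equal(rf$vcov, V)
})

test_that("a flat unit lag basis over L lags scales coefficients by L + 1", {
  spec <- crossbasis_spec(tspec5, lag_spline = "constant", max_lag = 2L)
  eta <- c(0.1, -0.2, 0.3, 0.05, -0.1)
  V <- diag(0.01, 5)
  rf <- reduce_coefficients(eta, V, spec, temps = seq(0, 30, by = 0.5))
  expect_equal(rf$beta, 3 * eta)
  expect_equal(rf$vcov, 9 * V)
})

test_that("reduced coefficients reproduce the brute-force lag-cumulated curve", {
  lag <- spline_spec("natural_cubic", log_lag_knots(5, 1), c(0, 5),
                     intercept = TRUE)  # v_l = 3
  spec <- crossbasis_spec(tspec5, lag_spline = lag, max_lag = 5L)
  set.seed(9)
  eta <- stats::rnorm(15, sd = 0.1)
  V <- crossprod(matrix(stats::rnorm(225, sd = 0.05), 15))
  rf <- reduce_coefficients(eta, V, spec, temps = seq(0, 30, by = 0.5))
  C <- lag_basis_matrix(spec)
  xs <- stats::runif(20, 0.5, 29.5)
  for (x in xs) {
    got <- drop(eval_spline(x, tspec5) %*% rf$beta)
    expect_equal(got, cum_curve_oracle(x, eta, tspec5, C, 5L),
                 tolerance = 1e-10)
  }
})

test_that("reduction preserves covariance symmetry and PSD", {
  lag <- spline_spec("natural_cubic", c(1.7), c(0, 7), intercept = TRUE)
  spec <- crossbasis_spec(tspec5, lag_spline = lag, max_lag = 7L)
  set.seed(10)
  for (rep in 1:10) {
    A <- matrix(stats::rnorm(15 * 15, sd = 0.1), 15)
    V <- crossprod(A)
    rf <- reduce_coefficients(stats::rnorm(15), V, spec,
                              temps = seq(0, 30, by = 0.5))
    expect_lt(max(abs(rf$vcov - t(rf$vcov))), 1e-12)
    ev <- eigen(rf$vcov, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})

test_that("dimension mismatches are conformability errors", {
  spec <- crossbasis_spec(tspec5, lag_spline = "constant", max_lag = 0L)
  expect_error(reduce_coefficients(1:4, diag(4), spec, temps = 0:30),
               "length 4")
  expect_error(reduce_coefficients(1:5, diag(4), spec, temps = 0:30),
               "5 x 5")
})

test_that("reduced_fit rejects invalid covariance inputs", {
  V <- diag(5); V[1, 2] <- 0.5  # asymmetric
  expect_error(reduced_fit(rep(0, 5), V, tspec5, temps = 0:30),
               "not symmetric")
  V2 <- diag(c(1, 1, 1, 1, -1))
  expect_error(reduced_fit(rep(0, 5), V2, tspec5, temps = 0:30),
               "positive semidefinite")
})
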