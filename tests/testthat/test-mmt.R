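test_that("the log relative-risk curve is linear in the coefficients", {
  fit <- toy_quadratic_fit()
  zero <- fit; zero$beta <- 0 * zero$beta
  expect_true(all(log_rr_curve(zero) == 0))
  double <- fit; double$beta <- 2 * double$beta
  expect_equal(log_rr_curve(double), 2 * log_rr_curve(fit), tolerance = 1e-12)
})

test_that("a projected quadratic curve is recovered exactly on the grid", {
  fit <- toy_quadratic_fit(center = 20, scale = 100)
  grid <- fit$temp_grid
  expect_equal(log_rr_curve(fit), (grid - 20)^2 / 100, tolerance = 1e-8)
  expect_error(log_rr_curve(fit, grid = 35), "outside the boundary")
})

test_that("argmin estimators find interior minima and honour the constraint", {
  fit <- toy_quadratic_fit(center = 20)
  expect_equal(argmin_mmt(fit), 20, tolerance = 1e-9)
  expect_equal(argmin_mmt(fit, constraint = c(1, 99)), 20, tolerance = 1e-9)

  # strictly decreasing curve: unconstrained argmin sits on the boundary,
  # the constrained one at the 99th percentile
  dec <- toy_quadratic_fit(center = 40, scale = 50, range = c(0, 30))
  expect_equal(argmin_mmt(dec), 30, tolerance = 1e-9)
  q99 <- unname(observed_percentiles(dec, 99))
  expect_lt(abs(argmin_mmt(dec, constraint = c(1, 99)) - q99),
            dec$grid_step + 1e-9)
})

test_that("the grid argmin agrees with a fine brute-force scan on a fitted replicate", {
  fx <- fitted_u_replicate()
  rf <- fx$fit$reduced
  fine <- seq(min(rf$temp_grid), max(rf$temp_grid), by = 0.001)
  brute <- fine[which.min(drop(eval_spline(fine, rf$temp_spline) %*% rf$beta))]
  expect_lt(abs(argmin_mmt(rf) - brute), rf$grid_step + 1e-9)
})

test_that("ties at equal minima break toward the lowest temperature", {
  fit <- toy_quadratic_fit()
  fit$beta <- 0 * fit$beta  # perfectly flat curve
  expect_equal(argmin_mmt(fit), min(fit$temp_grid))
})

test_that("a degenerate covariance collapses the MMT distribution to the argmin", {
  fit <- toy_quadratic_fit(center = 18)
  mr <- sample_mmt(fit, n_sim = 50, seed = 1)
  expect_true(all(mr$samples == argmin_mmt(fit)))
  expect_equal(unname(diff(mr$interval)), 0)
  expect_identical(mr$n_proposed, 50L)
})

test_that("a full-range prior support reproduces the unrestricted sample stream", {
  fx <- fitted_u_replicate()
  rf <- fx$fit$reduced
  e1 <- sample_mmt(rf, n_sim = 500, seed = 42)
  full <- prior_support(min(rf$temp_grid), max(rf$temp_grid), mode = "absolute")
  e2 <- sample_mmt(rf, n_sim = 500, prior = full, seed = 42)
  expect_identical(e2$samples, e1$samples)
  expect_identical(e2$beta_draws, e1$beta_draws)
  expect_identical(e2$interval, e1$interval)
})

test_that("the restricted sample is the unrestricted sample intersected with the support", {
  fx <- fitted_u_replicate()
  rf <- fx$fit$reduced
  e1 <- sample_mmt(rf, n_sim = 1000, seed = 77)
  pr <- prior_support(1, 99)
  e2 <- sample_mmt(rf, n_sim = 1000, prior = pr, seed = 77)
  bounds <- unname(observed_percentiles(rf, c(1, 99)))
  inside <- e1$samples[e1$samples >= bounds[1] & e1$samples <= bounds[2]]
  m <- length(inside)
  expect_gt(m, 0)
  expect_identical(e2$samples[seq_len(m)], inside)
  expect_true(all(e2$samples >= bounds[1] & e2$samples <= bounds[2]))
})

test_that("the acceptance fraction matches a two-pass estimate within Monte Carlo error", {
  fx <- fitted_u_replicate()
  rf <- fx$fit$reduced
  pr <- prior_support(40, 90)
  e2 <- sample_mmt(rf, n_sim = 10000, prior = pr, seed = 5)
  rate <- e2$n_accepted / e2$n_proposed
  e1 <- sample_mmt(rf, n_sim = 10000, seed = 6)  # independent stream
  bounds <- unname(observed_percentiles(rf, c(40, 90)))
  p_hat <- mean(e1$samples >= bounds[1] & e1$samples <= bounds[2])
  se <- sqrt(p_hat * (1 - p_hat) / 10000)
  expect_lt(abs(rate - p_hat), 5 * se + 1e-6)
})

test_that("an incompatible prior support fails loudly instead of short-sampling", {
  fit <- toy_quadratic_fit(center = 18)  # vcov = 0: all draws at 18
  pr <- prior_support(25, 28, mode = "absolute")
  expect_error(sample_mmt(fit, n_sim = 100, prior = pr, seed = 1,
                          budget_factor = 5), "incompatible")
  out <- prior_support(40, 50, mode = "absolute")
  expect_error(sample_mmt(fit, n_sim = 10, prior = out, seed = 1),
               "does not overlap")
})

test_that("empirical summaries use interpolated order statistics", {
  s <- summarize_mmt(1:5, percentile_pair = c(0, 100))
  expect_equal(s$point, 3)
  expect_equal(unname(s$interval), c(1, 5))
  s2 <- summarize_mmt(rep(4.2, 10), percentile_pair = c(2.5, 97.5))
  expect_equal(s2$point, 4.2)
  expect_equal(unname(s2$interval), c(4.2, 4.2))
  expect_error(summarize_mmt(numeric(0)), "Empty")
  expect_error(summarize_mmt(3), "at least 2")
})

test_that("normal quantiles are recovered from large samples", {
  set.seed(123)
  z <- stats::rnorm(10000)
  s <- summarize_mmt(z, percentile_pair = c(2.5, 97.5))
  expect_lt(abs(s$interval[1] - (-1.96)), 0.05)
  expect_lt(abs(s$interval[2] - 1.96), 0.05)
  expect_lt(abs(s$point), 0.05)
})

test_that("widening the percentile pair never narrows the interval", {
  set.seed(99)
  z <- stats::rgamma(500, shape = 2)
  pairs <- list(c(10, 90), c(5, 95), c(2.5, 97.5), c(0, 100))
  widths <- vapply(pairs, function(p) {
    unname(diff(summarize_mmt(z, percentile_pair = p)$interval))
  }, 0)
  expect_true(all(diff(widths) >= 0))
})

test_that("resummarizing swaps the percentile pair without re-drawing", {
  fx <- fitted_u_replicate()
  mr <- sample_mmt(fx$fit$reduced, n_sim = 500, seed = 8)
  adj <- resummarize_mmt(mr, percentile_pair = c(0, 95))
  expect_identical(adj$samples, mr$samples)
  expect_equal(unname(adj$interval),
               unname(stats::quantile(mr$samples, c(0, 0.95), type = 7)))
})
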