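test_that("true curves realize their stated minimum and shape class", {
  # u: argmin lands on the requested true MMT
  d <- generate_dataset(scenario_spec("u"), seed = 101)
  tr <- attr(d, "truth")
  expect_lt(abs(tr$true_mmt - 23.889), 0.05 + 1e-9)

  # sector: strictly increasing over the central 90% of the grid
  ds <- generate_dataset(scenario_spec("sector"), seed = 102)
  trs <- attr(ds, "truth")
  g <- seq(unname(stats::quantile(trs$metric_obs, .05)),
           unname(stats::quantile(trs$metric_obs, .95)), by = 0.05)
  expect_true(all(diff(trs$curve_fun(g)) > 0))

  # rotated-S: exactly two local minima on a fine grid, global at true MMT
  dr <- generate_dataset(scenario_spec("rotated_s"), seed = 103)
  trr <- attr(dr, "truth")
  fine <- seq(min(trr$metric_obs), max(trr$metric_obs), by = 0.001)
  cv <- trr$curve_fun(fine)
  dd <- diff(cv)
  n_min <- sum(diff(sign(dd)) > 0) + (dd[1] > 0) + (dd[length(dd)] < 0)
  expect_identical(n_min, 2L)
  expect_lt(abs(fine[which.min(cv)] - 29.167), 0.05 + 1e-9)
})

test_that("an unachievable template is a construction error", {
  basis <- spline_spec("quadratic_bspline", c(10, 20), c(0, 30))
  expect_error(make_true_curve("u", true_mmt = 45, basis, grid = seq(0, 30, 0.1)),
               "outside the boundary|unachievable")
})

test_that("temperature generation is seasonal, unbiased and reproducible", {
  flat <- generate_temperature(400, amplitude = 0, noise_sd = 0)
  expect_true(all(flat == flat[1]))

  long <- generate_temperature(3653, mean = 15, seed = 1)
  expect_lt(abs(mean(long) - 15), 0.5)

  expect_identical(generate_temperature(500, seed = 7),
                   generate_temperature(500, seed = 7))
})

test_that("count draws have variance phi times the mean", {
  set.seed(42)
  y1 <- draw_counts(rep(10, 1e5), phi = 1)
  expect_true(all(y1 >= 0) && all(y1 == round(y1)))
  expect_gt(stats::var(y1) / mean(y1), 0.97)
  expect_lt(stats::var(y1) / mean(y1), 1.03)

  y2 <- draw_counts(rep(10, 1e5), phi = 2)
  expect_gt(stats::var(y2) / mean(y2), 1.9)
  expect_lt(stats::var(y2) / mean(y2), 2.1)

  expect_error(draw_counts(10, phi = 0.8), ">= 1")
})

test_that("datasets carry their generative truth and reproduce under the same seed", {
  sc <- scenario_spec("u", n_years = 2)
  d1 <- generate_dataset(sc, seed = 9)
  d2 <- generate_dataset(sc, seed = 9)
  expect_identical(d1$deaths, d2$deaths)
  expect_identical(d1$temperature, d2$temperature)
  tr <- attr(d1, "truth")
  expect_length(tr$mu, nrow(d1))
  expect_true(all(d1$deaths >= 0))
})

test_that("a single-replicate study is deterministic given its seed", {
  sc <- scenario_spec("u", n_years = 2)
  s1 <- run_study(sc, 1, methods = c("argmin2", "empirical1"), n_sim = 200,
                  seed = 5)
  s2 <- run_study(sc, 1, methods = c("argmin2", "empirical1"), n_sim = 200,
                  seed = 5)
  expect_identical(s1$estimates, s2$estimates)
  expect_identical(s1$seeds$replicates, s2$seeds$replicates)
})

test_that("a vacuous prior reproduces the unrestricted study exactly", {
  sc <- scenario_spec("u", n_years = 2)
  full <- prior_support(-100, 100, mode = "absolute")
  s1 <- run_study(sc, 3, methods = "empirical1", n_sim = 200, seed = 6,
                  compute_rr = FALSE)
  s2 <- run_study(sc, 3, methods = "empirical2", n_sim = 200, seed = 6,
                  prior = full, compute_rr = FALSE)
  expect_equal(s1$estimates$mmt, s2$estimates$mmt)
  expect_equal(s1$estimates$mmt_lo, s2$estimates$mmt_lo)
  expect_equal(s1$estimates$mmt_hi, s2$estimates$mmt_hi)
})

test_that("a stricter support never lengthens the interval, per replicate", {
  sc <- scenario_spec("u", n_years = 2)
  full <- prior_support(-100, 100, mode = "absolute")
  strict <- prior_support(10, 99)
  s_full <- run_study(sc, 5, methods = "empirical2", n_sim = 300, seed = 8,
                      prior = full, compute_rr = FALSE)
  s_strict <- run_study(sc, 5, methods = "empirical2", n_sim = 300, seed = 8,
                        prior = strict, compute_rr = FALSE)
  len_full <- s_full$estimates$mmt_hi - s_full$estimates$mmt_lo
  len_strict <- s_strict$estimates$mmt_hi - s_strict$estimates$mmt_lo
  expect_true(all(len_strict <= len_full + 1e-9))
})

test_that("metric arithmetic matches hand-computed cases", {
  est <- tibble::tibble(method = "m", mmt = c(2, 2), mmt_lo = NA_real_,
                        mmt_hi = NA_real_)
  m0 <- compute_metrics(est, truth = 2)
  expect_equal(m0$bias, 0)
  expect_equal(m0$rmse, 0)
  expect_true(is.na(m0$coverage_pct))

  est1 <- tibble::tibble(method = "m", mmt = c(1, 3), mmt_lo = NA_real_,
                         mmt_hi = NA_real_)
  m1 <- compute_metrics(est1, truth = 2)
  expect_equal(m1$bias, 0)
  expect_equal(m1$rmse, 1)

  est2 <- tibble::tibble(method = "m", mmt = c(2, 4),
                         mmt_lo = c(0, 3), mmt_hi = c(4, 5))
  m2 <- compute_metrics(est2, truth = 2)
  expect_equal(m2$coverage_pct, 50)
  expect_equal(m2$mean_length, 3)
})

test_that("RMSE squared decomposes into bias squared plus variance", {
  set.seed(77)
  for (rep in 1:10) {
    est <- tibble::tibble(method = "m", mmt = stats::rnorm(50, 20, 3),
                          mmt_lo = NA_real_, mmt_hi = NA_real_)
    m <- compute_metrics(est, truth = 20)
    v <- mean((est$mmt - mean(est$mmt))^2)  # population variance
    expect_equal(m$rmse^2, m$bias^2 + v, tolerance = 1e-10)
    expect_gte(m$rmse, abs(m$bias))
  }
})

test_that("scenario priors follow the stated percentile supports", {
  p <- scenario_prior("sector", "strong")
  expect_equal(c(p$lower, p$upper), c(1, 10))
  p2 <- scenario_prior("rotated_s", "moderate")
  expect_equal(c(p2$lower, p2$upper), c(50, 99))
  p3 <- scenario_prior("reverse_j", "minimal")
  expect_equal(c(p3$lower, p3$upper), c(1, 99))
})

test_that("study metrics cover MMT and both relative risks", {
  sc <- scenario_spec("u", n_years = 2)
  st <- run_study(sc, 3, methods = c("argmin2", "empirical1"), n_sim = 200,
                  seed = 10)
  m <- study_metrics(st)
  expect_setequal(unique(m$quantity), c("mmt", "rr_cold", "rr_heat"))
  expect_identical(nrow(m), 6L)
  expect_true(all(m$coverage_pct >= 0 & m$coverage_pct <= 100, na.rm = TRUE))
  expect_true(all(m$rmse >= abs(m$bias) - 1e-12))
})
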