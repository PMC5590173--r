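#' Synthetic temperature-mortality scenario
#'
#' A generative truth for the simulation harness: an association shape with
#' a known true MMT, an overdispersion level, and the temperature-series
#' and confounder structure of a multi-year daily mortality series. The
#' four shapes cover the qualitative patterns seen in city-level analyses:
#' \describe{
#'   \item{`"u"`}{both arms rising from an interior minimum (default true
#'     MMT 23.889 degC, a warm-season minimum);}
#'   \item{`"reverse_j"`}{rising cold arm, long flat bottom to the right of
#'     the minimum (11.274 degC) and a steep short hot arm;}
#'   \item{`"rotated_s"`}{global minimum at high temperature (29.167 degC)
#'     with the extreme-cold arm turning back down, leaving a second local
#'     minimum at the cold boundary;}
#'   \item{`"sector"`}{monotone-increasing risk from the cold end, minimum
#'     near the cold boundary (-3.333 degC).}
#' }
#' Curve amplitudes default to cold/heat relative risks of realistic
#' magnitude at the 1st/99th temperature percentiles (about 1.02-1.19,
#' the scale typical of city-level temperature-mortality associations).
#'
#' @param shape One of `"u"`, `"reverse_j"`, `"rotated_s"`, `"sector"`.
#' @param true_mmt True minimum mortality temperature, degC. Defaults per
#'   shape as above.
#' @param dispersion Overdispersion phi >= 1 (variance = phi * mean);
#'   default 1.3.
#' @param n_years Years of daily data per replicate (default 5).
#' @param baseline_log_rate Log expected deaths/day at the MMT on an
#'   average day (default `log(150)`, a large-city scale).
#' @param temp_mean,temp_amplitude,temp_noise_sd,temp_ar Annual-cycle mean
#'   and amplitude (degC; defaults 15 and 14), marginal standard deviation and lag-1
#'   autocorrelation of the AR(1) day-to-day noise.
#' @param dow_effects Length-7 log-rate day-of-week effects (Sunday first).
#' @param season_amplitude Amplitude of the smooth seasonal mortality term
#'   on the log scale (winter peak), default 0.12.
#' @param ma_window Moving-average window (days) of the temperature metric;
#'   defaults per shape (3, 2, 4, 1 days for u, reverse-J, rotated-S,
#'   sector).
#' @param rr_cold,rr_heat Target relative risks at the 1st/99th exposure
#'   percentiles used to scale the curve template (defaults per shape).
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("u", n_years = 2)
#' @export
scenario_spec <- function(shape = c("u", "reverse_j", "rotated_s", "sector"),
                          true_mmt = NULL,
                          dispersion = 1.3,
                          n_years = 5,
                          baseline_log_rate = log(150),
                          temp_mean = 15, temp_amplitude = 14,
                          temp_noise_sd = 4.5, temp_ar = 0.6,
                          dow_effects = c(0.015, 0.02, 0, -0.005, -0.005, 0, 0.005),
                          season_amplitude = 0.12,
                          ma_window = NULL,
                          rr_cold = NULL, rr_heat = NULL) {
  shape <- match.arg(shape)
  defaults <- list(
    u         = list(mmt = 23.889, window = 3L, cold = 1.094, heat = 1.079),
    reverse_j = list(mmt = 11.274, window = 2L, cold = 1.023, heat = 1.118),
    rotated_s = list(mmt = 29.167, window = 4L, cold = 1.070, heat = 1.015),
    sector    = list(mmt = -3.333, window = 1L, cold = 1.000, heat = 1.185)
  )[[shape]]
  true_mmt <- true_mmt %||% defaults$mmt
  ma_window <- as.integer(ma_window %||% defaults$window)
  rr_cold <- rr_cold %||% defaults$cold
  rr_heat <- rr_heat %||% defaults$heat
  if (dispersion < 1) stop("`dispersion` must be >= 1.", call. = FALSE)
  stopifnot(n_years >= 1, ma_window >= 1L, rr_cold >= 1, rr_heat >= 1)
  structure(
    list(shape = shape, true_mmt = true_mmt, dispersion = dispersion,
         n_years = n_years, baseline_log_rate = baseline_log_rate,
         temp_mean = temp_mean, temp_amplitude = temp_amplitude,
         temp_noise_sd = temp_noise_sd, temp_ar = temp_ar,
         dow_effects = dow_effects, season_amplitude = season_amplitude,
         ma_window = ma_window, rr_cold = rr_cold, rr_heat = rr_heat),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s shape, true MMT %.3f degC, phi %.2f, %g years, %d-day MA metric\n",
              x$shape, x$true_mmt, x$dispersion, x$n_years, x$ma_window))
  invisible(x)
}

#' Synthetic daily temperature series
#'
#' Sinusoidal annual cycle (peak in mid-July) plus AR(1) day-to-day noise
#' with a stated marginal standard deviation.
#'
#' @param n_days Number of days (>= 365).
#' @param mean,amplitude Annual-cycle mean and amplitude, degC.
#' @param noise_sd Marginal standard deviation of the AR(1) noise, degC.
#' @param ar Lag-1 autocorrelation in \[0, 1).
#' @param seed Optional integer seed.
#' @param peak_day Day of year of the warm peak (default 196, mid-July).
#' @return Numeric vector of daily mean temperatures.
#' @export
generate_temperature <- function(n_days, mean = 15, amplitude = 14,
                                 noise_sd = 4.5, ar = 0.6, seed = NULL,
                                 peak_day = 196) {
  stopifnot(n_days >= 365, noise_sd >= 0, ar >= 0, ar < 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  t <- seq_len(n_days)
  seasonal <- mean + amplitude * cos(2 * pi * (t - peak_day) / 365.25)
  if (noise_sd > 0) {
    innov_sd <- noise_sd * sqrt(1 - ar^2)
    e <- as.numeric(stats::filter(stats::rnorm(n_days, 0, innov_sd), ar,
                                  method = "recursive"))
  } else {
    e <- numeric(n_days)
  }
  seasonal + e
}

#' Construct true-curve coefficients for a scenario shape
#'
#' Builds a smooth template curve of the requested shape and projects it
#' onto the temperature basis by least squares over a fine grid, subject to
#' a zero-derivative constraint at `true_mmt` so the projected curve is
#' stationary exactly there; a small quadratic well (escalated from a
#' negligible depth) anchors the global minimum for near-flat shapes. The
#' realized fine-grid argmin is verified against `true_mmt` and the
#' construction errors if it cannot be achieved on the basis. The returned
#' coefficients define the generative truth; the realized curve (not the
#' template) is the truth the harness scores against.
#'
#' @param shape Scenario shape (see [scenario_spec()]).
#' @param true_mmt Required true MMT, degC.
#' @param basis A [spline_spec()] rich enough to express the shape.
#' @param grid Temperature grid spanning the intended evaluation range.
#' @param temps Optional reference exposure series for percentile-based
#'   template scales; defaults to the grid.
#' @param rr_cold,rr_heat Template amplitude targets at the 1st/99th
#'   percentiles.
#' @param tol Maximum allowed distance between the realized argmin and
#'   `true_mmt` (default one step of `grid`).
#' @return List with `beta` (basis coefficients), `intercept` (constant
#'   making the curve minimum zero), `true_mmt` (realized fine-grid
#'   argmin), `rr_cold`, `rr_heat` (realized RRs at the 1st/99th
#'   percentiles), and `curve_fun` (vectorized curve function).
#' @export
make_true_curve <- function(shape, true_mmt, basis, grid, temps = NULL,
                            rr_cold = NULL, rr_heat = NULL, tol = NULL) {
  shape <- match.arg(shape, c("u", "reverse_j", "rotated_s", "sector"))
  stopifnot(inherits(basis, "spline_spec"))
  grid <- sort(as.numeric(grid))
  step <- if (length(grid) > 1) min(diff(grid)) else 0.1
  tol <- tol %||% step
  if (is.null(temps)) temps <- grid
  q <- stats::quantile(temps, c(.01, .10, .25, .50, .75, .90, .99), type = 7)
  names(q) <- c("q1", "q10", "q25", "q50", "q75", "q90", "q99")
  tmin <- min(grid); tmax <- max(grid)
  defaults <- list(u = c(1.094, 1.079), reverse_j = c(1.023, 1.118),
                   rotated_s = c(1.070, 1.015), sector = c(1.000, 1.185))[[shape]]
  rr_cold <- rr_cold %||% defaults[1]
  rr_heat <- rr_heat %||% defaults[2]

  template <- function(x, m) {
    switch(shape,
      u = {
        ac <- log(rr_cold); ah <- log(rr_heat)
        ac * (pmax(m - x, 0) / max(m - q["q1"], 1))^2 +
          ah * (pmax(x - m, 0) / max(q["q99"] - m, 1))^2
      },
      reverse_j = {
        eps <- 0.004
        qh <- m + 0.55 * (q["q99"] - m)
        ac <- max(log(rr_cold) - eps * ((q["q1"] - m) / (q["q99"] - m))^2, 0.001)
        ah <- max(log(rr_heat) - eps, 0.001)
        ac * (pmax(m - x, 0) / max(m - q["q1"], 1))^2 +
          ah * (pmax(x - qh, 0) / max(q["q99"] - qh, 0.5))^3 +
          eps * ((x - m) / max(q["q99"] - m, 1))^2
      },
      rotated_s = {
        # smooth interpolant through the shape's landmarks: cold-boundary
        # downturn, local maximum near the 10th percentile, long descent,
        # shallow plateau, global minimum at m, short hot-arm rise
        ctrl_x <- c(tmin, q["q10"], q["q25"], q["q50"], q["q75"], m, tmax)
        ctrl_y <- c(0.05, 0.11, 0.095, 0.05, 0.02, 0, 0.035)
        keep <- c(ctrl_x[-c(6, 7)] < m - 1, TRUE, TRUE)
        ctrl_x <- ctrl_x[keep]; ctrl_y <- ctrl_y[keep]
        Tfun <- stats::splinefun(ctrl_x, ctrl_y, method = "natural")
        sc <- log(rr_cold) / max(Tfun(q["q1"]), 0.01)
        sc * Tfun(x)
      },
      sector = {
        ah <- log(rr_heat); ac <- 0.01
        ah * (pmax(x - m, 0) / max(q["q99"] - m, 1))^2 +
          ac * (pmax(m - x, 0) / max(m - tmin, 0.5))^2
      }
    )
  }

  fine <- seq(tmin, tmax, by = 0.001)
  B_fit <- eval_spline(grid, basis)
  B_fine <- eval_spline(fine, basis)

  # Constrained least-squares projection: fit the template on the basis
  # subject to a zero-derivative constraint at the true MMT, so the
  # projected curve is stationary exactly there even for near-flat shapes.
  h <- 1e-4 * (tmax - tmin)
  g <- drop(eval_spline(true_mmt + h, basis, extrapolation = "extend") -
              eval_spline(true_mmt - h, basis, extrapolation = "extend")) / (2 * h)
  A <- c(0, g)                                    # intercept has zero slope
  N <- qr.Q(qr(matrix(A, ncol = 1)), complete = TRUE)[, -1L, drop = FALSE]
  Xall <- cbind(1, B_fit)
  y0 <- template(grid, true_mmt)
  # Near-flat shapes can leave the global minimum of the projection away
  # from the stationary point; a small quadratic well at the true MMT
  # (escalated geometrically from a negligible depth) anchors it without
  # visibly changing the shape class.
  sw <- (tmax - tmin) / 2
  achieved <- NA_real_
  for (lambda in c(0, 0.001 * 2^(0:9))) {
    y <- y0 + lambda * ((grid - true_mmt) / sw)^2
    gamma <- stats::lsfit(Xall %*% N, y, intercept = FALSE)$coefficients
    cf <- drop(N %*% gamma)
    beta <- unname(cf[-1L])
    curve_fine <- drop(B_fine %*% beta)
    achieved <- fine[which.min(curve_fine)]
    if (abs(achieved - true_mmt) <= tol) break
  }
  if (abs(achieved - true_mmt) > tol) {
    stop(sprintf("Shape template unachievable on this basis: realized argmin %.3f misses true MMT %.3f by more than %g.",
                 achieved, true_mmt, tol), call. = FALSE)
  }
  intercept <- -min(curve_fine)
  curve_fun <- function(x) {
    drop(eval_spline(x, basis, extrapolation = "extend") %*% beta) + intercept
  }
  f_m <- curve_fun(achieved)
  list(beta = beta,
       intercept = intercept,
       true_mmt = achieved,
       rr_cold = exp(curve_fun(unname(q["q1"])) - f_m),
       rr_heat = exp(curve_fun(unname(q["q99"])) - f_m),
       curve_fun = curve_fun,
       basis = basis)
}

#' Generate a synthetic daily mortality dataset
#'
#' Draws a full replicate from a [scenario_spec()]: a seasonal AR(1)
#' temperature series, the true association curve applied to the
#' moving-averaged temperature metric, day-of-week and smooth seasonal
#' mortality confounding, and overdispersed counts with variance
#' phi * mean. Counts are drawn from a negative binomial with
#' per-observation size mu/(phi - 1), which matches the quasi-Poisson
#' variance exactly and degenerates to Poisson at phi = 1.
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `date`, `deaths`, `temperature`, carrying
#'   the generative truth in `attr(, "truth")` (true beta, basis, realized
#'   true MMT and RRs, expected counts `mu`, and the exposure metric).
#' @export
generate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_days <- round(365.25 * spec$n_years)
  temps <- generate_temperature(n_days, mean = spec$temp_mean,
                                amplitude = spec$temp_amplitude,
                                noise_sd = spec$temp_noise_sd,
                                ar = spec$temp_ar)
  dates <- seq(as.Date("2000-01-01"), by = "day", length.out = n_days)
  truth <- scenario_truth(spec, temps)
  mu <- scenario_mu(spec, temps, dates, truth)
  deaths <- draw_counts(mu, spec$dispersion)
  out <- tibble::tibble(date = dates, deaths = deaths, temperature = temps)
  attr(out, "truth") <- c(truth, list(mu = mu))
  attr(out, "scenario") <- spec
  out
}

# The generative truth induced by a scenario on a concrete temperature
# series: basis knots at the 10th/75th/90th percentiles of the observed
# moving-average metric (the same construction the fitted model uses, so
# the fit is correctly specified), true coefficients from the shape
# template.
scenario_truth <- function(spec, temps) {
  L <- spec$ma_window - 1L
  metric <- .trailing_mean(temps, spec$ma_window)
  metric_obs <- metric[(L + 1L):length(metric)]
  knots <- unname(stats::quantile(metric_obs, c(.10, .75, .90), type = 7))
  basis <- spline_spec("quadratic_bspline", internal_knots = knots,
                       boundary_knots = range(metric_obs), intercept = FALSE)
  grid <- seq(min(metric_obs), max(metric_obs), by = 0.05)
  curve <- make_true_curve(spec$shape, spec$true_mmt, basis, grid,
                           temps = metric_obs,
                           rr_cold = spec$rr_cold, rr_heat = spec$rr_heat,
                           tol = 0.05)
  c(curve, list(metric = metric, metric_obs = metric_obs, max_lag = L))
}

# Expected counts: baseline + true curve at the exposure metric + day of
# week + smooth seasonal mortality (winter peak). The first L days use a
# shortened trailing window for the metric; they are dropped at fitting
# time in any case.
scenario_mu <- function(spec, temps, dates, truth) {
  n <- length(temps)
  metric <- truth$metric
  head_idx <- which(is.na(metric))
  if (length(head_idx)) {
    metric[head_idx] <- vapply(head_idx, function(i) mean(temps[1:i]), 0)
  }
  f <- truth$curve_fun(metric)
  dow <- as.integer(format(dates, "%w")) + 1L
  season <- spec$season_amplitude * cos(2 * pi * (seq_len(n) - 15) / 365.25)
  exp(spec$baseline_log_rate + f + spec$dow_effects[dow] + season)
}

#' Draw overdispersed counts with variance phi * mean
#'
#' Negative-binomial mechanism with per-observation size mu/(phi - 1)
#' (exact quasi-Poisson variance); Poisson when phi = 1.
#'
#' @param mu Vector of expected counts.
#' @param phi Dispersion (>= 1).
#' @return Integer vector of counts.
#' @export
draw_counts <- function(mu, phi) {
  if (phi < 1) stop("`phi` must be >= 1.", call. = FALSE)
  if (phi == 1) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), size = mu / (phi - 1), mu = mu)
  }
}

#' Default uniform prior supports per scenario shape
#'
#' Percentile supports for the restricted sampler at three informativity
#' levels. Strong supports: 70th-95th percentiles for the u and rotated-S
#' shapes, 40th-65th for reverse-J, 1st-10th for sector. Moderate:
#' 50th-99th (u, rotated-S), 30th-80th (reverse-J), 1st-50th (sector).
#' Minimal: 1st-99th for all shapes.
#'
#' @param shape Scenario shape.
#' @param level `"minimal"`, `"moderate"`, or `"strong"`.
#' @return A [prior_support()] in percentile mode.
#' @export
scenario_prior <- function(shape, level = c("minimal", "moderate", "strong")) {
  shape <- match.arg(shape, c("u", "reverse_j", "rotated_s", "sector"))
  level <- match.arg(level)
  p <- switch(level,
    minimal = c(1, 99),
    moderate = switch(shape, u = , rotated_s = c(50, 99),
                      reverse_j = c(30, 80), sector = c(1, 50)),
    strong = switch(shape, u = , rotated_s = c(70, 95),
                    reverse_j = c(40, 65), sector = c(1, 10))
  )
  prior_support(p[1], p[2], mode = "percentile")
}

#' Run a simulation study over replicated synthetic datasets
#'
#' The estimator-evaluation harness: one temperature/confounder realization
#' is generated per study and held fixed (the covariates are part of the
#' design), and each replicate redraws the mortality counts from the true
#' expected counts, refits the quasi-Poisson model with the generating
#' basis, and applies the requested MMT estimators and the cold/heat
#' relative risks. Replicate-level fit failures are recorded with a status
#' and excluded from metrics, never silently dropped.
#'
#' @param spec A [scenario_spec()].
#' @param n_replicates Number of replicate datasets.
#' @param methods Subset of `"argmin1"`, `"argmin2"`, `"empirical1"`,
#'   `"empirical2"`.
#' @param n_sim Monte Carlo draws per replicate for the empirical methods
#'   (default 2000).
#' @param prior [prior_support()] for `"empirical2"`; defaults to the
#'   minimally informative 1st-99th percentile support.
#' @param percentile_pair Interval percentiles (default `c(2.5, 97.5)`).
#' @param seed Master seed; spawns one substream per replicate plus one for
#'   the shared covariate realization (all recorded in the result).
#' @param compute_rr Also compute cold/heat relative risks per replicate
#'   (default TRUE).
#' @param grid_step Argmin grid resolution (default 0.1 degC).
#' @return An object of class `mmt_study`: list with `estimates` (tibble,
#'   one row per replicate x method), `truth`, `spec`, `seeds`,
#'   `n_failed`.
#' @export
run_study <- function(spec, n_replicates, methods = c("argmin2", "empirical1"),
                      n_sim = 2000L, prior = NULL,
                      percentile_pair = c(2.5, 97.5),
                      seed = 1L, compute_rr = TRUE, grid_step = 0.1) {
  stopifnot(inherits(spec, "scenario_spec"), n_replicates >= 1)
  methods <- match.arg(methods,
                       c("argmin1", "argmin2", "empirical1", "empirical2"),
                       several.ok = TRUE)
  if ("empirical2" %in% methods && is.null(prior)) {
    prior <- scenario_prior(spec$shape, "minimal")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  covariate_seed <- sample.int(2^31 - 2, 1L)
  rep_seeds <- sample.int(2^31 - 2, n_replicates)
  mc_seeds <- sample.int(2^31 - 2, n_replicates)

  base <- generate_dataset(spec, seed = covariate_seed)
  truth <- attr(base, "truth")
  mu <- truth$mu
  L <- truth$max_lag
  n_days <- nrow(base)

  # fixed design blocks, shared across replicates
  cbspec <- crossbasis_spec(truth$basis, lag_spline = "ma", max_lag = L)
  cb <- build_crossbasis(base$temperature, cbspec)
  conf <- build_confounders(base$date, df_per_year = 8)

  rows <- vector("list", n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    y <- draw_counts(mu, spec$dispersion)
    d <- tibble::tibble(date = base$date, deaths = y,
                        temperature = base$temperature)
    res <- tryCatch({
      fit <- fit_quasipoisson(d, cb, conf)
      reduced <- reduce_coefficients(fit$eta_hat, fit$vcov_eta, cbspec,
                                     temps = truth$metric_obs,
                                     grid_step = grid_step)
      out <- list()
      emp <- list()
      for (m in methods) {
        if (m %in% c("argmin1", "argmin2")) {
          pt <- argmin_mmt(reduced,
                           constraint = if (m == "argmin2") c(1, 99) else NULL)
          row <- tibble::tibble(method = m, mmt = pt,
                                mmt_lo = NA_real_, mmt_hi = NA_real_,
                                n_proposed = NA_integer_, n_accepted = NA_integer_)
          if (compute_rr) {
            rr <- cold_heat_rr(reduced, pt)
            row <- dplyr::bind_cols(row, .rr_cols(rr))
          }
        } else {
          mr <- sample_mmt(reduced, n_sim = n_sim,
                           prior = if (m == "empirical2") prior else NULL,
                           seed = mc_seeds[r],
                           percentile_pair = percentile_pair)
          row <- tibble::tibble(method = m, mmt = mr$point,
                                mmt_lo = mr$interval[1], mmt_hi = mr$interval[2],
                                n_proposed = mr$n_proposed,
                                n_accepted = mr$n_accepted)
          if (compute_rr) {
            rr <- cold_heat_rr(reduced, mr, percentile_pair = percentile_pair)
            row <- dplyr::bind_cols(row, .rr_cols(rr))
          }
        }
        out[[m]] <- row
      }
      dplyr::bind_rows(out) |>
        dplyr::mutate(replicate = r, seed = rep_seeds[r],
                      dispersion_hat = fit$dispersion, status = "ok",
                      .before = 1)
    }, error = function(e) {
      tibble::tibble(replicate = r, seed = rep_seeds[r],
                     dispersion_hat = NA_real_,
                     status = paste0("failed: ", conditionMessage(e)),
                     method = methods, mmt = NA_real_,
                     mmt_lo = NA_real_, mmt_hi = NA_real_,
                     n_proposed = NA_integer_, n_accepted = NA_integer_)
    })
    if (!all(res$status == "ok")) n_failed <- n_failed + 1L
    rows[[r]] <- res
  }
  structure(
    list(estimates = dplyr::bind_rows(rows),
         truth = list(true_mmt = truth$true_mmt,
                      rr_cold = truth$rr_cold, rr_heat = truth$rr_heat,
                      beta = truth$beta, basis = truth$basis),
         spec = spec,
         seeds = list(master = seed, covariate = covariate_seed,
                      replicates = rep_seeds, monte_carlo = mc_seeds),
         n_sim = n_sim, prior = prior, percentile_pair = percentile_pair,
         n_failed = n_failed),
    class = "mmt_study"
  )
}

.rr_cols <- function(rr) {
  tibble::tibble(
    rr_cold = rr$cold$point, rr_cold_lo = rr$cold$interval[1],
    rr_cold_hi = rr$cold$interval[2],
    rr_heat = rr$heat$point, rr_heat_lo = rr$heat$interval[1],
    rr_heat_hi = rr$heat$interval[2]
  )
}

#' @export
print.mmt_study <- function(x, ...) {
  cat(sprintf("<mmt_study> %s scenario, %d replicates (%d failed), methods: %s\n",
              x$spec$shape,
              length(unique(x$estimates$replicate)), x$n_failed,
              paste(unique(x$estimates$method), collapse = ", ")))
  invisible(x)
}

#' Bias, RMSE, coverage and interval length of replicated estimates
#'
#' Per-method estimator metrics against a known truth: mean bias
#' (mean of estimate - truth), root mean squared error, coverage
#' probability (percent of intervals containing the truth; `NA` for
#' point-only methods) and mean interval length.
#'
#' @param estimates A data frame of per-replicate estimates (e.g.
#'   `run_study(...)$estimates`), one row per replicate x method.
#' @param truth The true parameter value.
#' @param estimate,lower,upper Column names (strings) holding the point
#'   estimate and interval endpoints; defaults target the MMT columns.
#' @return A tibble with one row per method: `method`, `bias`, `rmse`,
#'   `coverage_pct`, `mean_length`, `n_replicates`.
#' @export
compute_metrics <- function(estimates, truth, estimate = "mmt",
                            lower = "mmt_lo", upper = "mmt_hi") {
  stopifnot(is.data.frame(estimates), is.numeric(truth), length(truth) == 1L)
  df <- estimates
  if ("status" %in% names(df)) df <- dplyr::filter(df, .data$status == "ok")
  df |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      bias = mean(.data[[estimate]] - truth),
      rmse = sqrt(mean((.data[[estimate]] - truth)^2)),
      coverage_pct = if (all(is.na(.data[[lower]]))) NA_real_ else
        100 * mean(.data[[lower]] <= truth & truth <= .data[[upper]]),
      mean_length = if (all(is.na(.data[[lower]]))) NA_real_ else
        mean(.data[[upper]] - .data[[lower]]),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Metric table for a simulation study
#'
#' Applies [compute_metrics()] to the MMT and, when present, to the cold-
#' and heat-related relative risks of a study, against the study's realized
#' truths.
#'
#' @param study An [run_study()] result.
#' @return A tibble with one row per (quantity, method): columns
#'   `scenario`, `quantity`, `truth`, then the metric columns.
#' @export
study_metrics <- function(study) {
  stopifnot(inherits(study, "mmt_study"))
  est <- study$estimates
  blocks <- list(
    mmt = list(truth = study$truth$true_mmt, cols = c("mmt", "mmt_lo", "mmt_hi"))
  )
  if ("rr_cold" %in% names(est)) {
    blocks$rr_cold <- list(truth = study$truth$rr_cold,
                           cols = c("rr_cold", "rr_cold_lo", "rr_cold_hi"))
    blocks$rr_heat <- list(truth = study$truth$rr_heat,
                           cols = c("rr_heat", "rr_heat_lo", "rr_heat_hi"))
  }
  purrr::imap_dfr(blocks, function(b, nm) {
    compute_metrics(est, b$truth, b$cols[1], b$cols[2], b$cols[3]) |>
      dplyr::mutate(scenario = study$spec$shape, quantity = nm,
                    truth = b$truth, .before = 1)
  })
}

#' @export
tidy.mmt_study <- function(x, ...) study_metrics(x)

#' @export
glance.mmt_study <- function(x, ...) {
  tibble::tibble(
    scenario = x$spec$shape,
    true_mmt = x$truth$true_mmt,
    n_replicates = length(unique(x$estimates$replicate)),
    n_failed = x$n_failed,
    n_sim = x$n_sim,
    dispersion = x$spec$dispersion,
    n_years = x$spec$n_years
  )
}
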