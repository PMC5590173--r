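#' Confounder design: day of week and smooth time trend
#'
#' Builds the standard confounder block for daily mortality time series:
#' six day-of-week indicator contrasts (Sunday as the reference level) and a
#' natural cubic spline of the day index with `df_per_year` degrees of
#' freedom per year of data (rounded to the nearest integer over the whole
#' period), absorbing seasonality and long-term trends.
#'
#' @param dates A `Date` vector of consecutive calendar days.
#' @param df_per_year Degrees of freedom per year for the time spline
#'   (default 8).
#' @param extra_terms Optional numeric matrix of additional columns, one row
#'   per day.
#' @return An object of class `confounder_design`: a list with the combined
#'   design `matrix` (no intercept column), `n_years`, and `df_time`.
#' @export
build_confounders <- function(dates, df_per_year = 8, extra_terms = NULL) {
  dates <- as.Date(dates)
  n <- length(dates)
  if (n < 365L) stop("Need at least one year of dates.", call. = FALSE)
  if (any(diff(as.integer(dates)) != 1L)) {
    stop("`dates` must be consecutive calendar days.", call. = FALSE)
  }
  n_years <- n / 365.25
  df_time <- max(1L, as.integer(round(df_per_year * n_years)))

  dow <- factor(format(dates, "%w"), levels = as.character(0:6))
  dow_mat <- stats::model.matrix(~dow)[, -1L, drop = FALSE]
  colnames(dow_mat) <- paste0("dow", 1:6)

  t_idx <- seq_len(n)
  time_mat <- unclass(splines::ns(t_idx, df = df_time))
  colnames(time_mat) <- paste0("time", seq_len(ncol(time_mat)))

  mat <- cbind(dow_mat, time_mat)
  if (!is.null(extra_terms)) {
    extra_terms <- as.matrix(extra_terms)
    stopifnot(nrow(extra_terms) == n)
    if (is.null(colnames(extra_terms))) {
      colnames(extra_terms) <- paste0("extra", seq_len(ncol(extra_terms)))
    }
    mat <- cbind(mat, extra_terms)
  }
  structure(list(matrix = mat, n_years = n_years, df_time = df_time,
                 df_per_year = df_per_year),
            class = "confounder_design")
}

#' @export
print.confounder_design <- function(x, ...) {
  cat(sprintf("<confounder_design> %d rows: 6 day-of-week contrasts + %d time-spline df (%.2f years)\n",
              nrow(x$matrix), x$df_time, x$n_years))
  invisible(x)
}

#' Fit the quasi-Poisson mortality model
#'
#' Fits the log-linear overdispersed count model
#' \deqn{\log \mu_t = \alpha + s(x_t; \eta) + \sum_j h_j(u_{jt}; \gamma_j)}
#' by quasi-Poisson GLM: the point estimates coincide with the Poisson MLE
#' and the covariance is inflated by the Pearson overdispersion estimate
#' \eqn{\hat\phi = \chi^2_{Pearson} / (n - p)}. Days lacking a complete lag
#' history (the first `max_lag` days) are dropped from the outcome and the
#' confounder block to align with the cross-basis rows.
#'
#' @param data A data frame with columns `date`, `deaths`, `temperature`
#'   (see [read_timeseries()]); only `deaths` is used here, aligned by row.
#' @param crossbasis Design matrix from [build_crossbasis()].
#' @param confounders A [build_confounders()] design (rows matching `data`).
#' @return An object of class `qp_fit`: list with `eta_hat`, `vcov_eta`,
#'   `gamma_hat` (intercept + confounder coefficients), `dispersion`,
#'   `converged`, `n_obs`, `fitted`, `glm` (the underlying `glm` object).
#' @export
fit_quasipoisson <- function(data, crossbasis, confounders) {
  stopifnot(is.data.frame(data), inherits(confounders, "confounder_design"))
  y <- data$deaths
  if (is.null(y)) stop("`data` must have a `deaths` column.", call. = FALSE)
  if (any(y < 0) || any(y != round(y))) {
    stop("`deaths` must be nonnegative integers.", call. = FALSE)
  }
  L <- attr(crossbasis, "rows_dropped") %||% 0L
  keep <- (L + 1L):length(y)
  if (nrow(crossbasis) != length(keep)) {
    stop("Cross-basis rows do not align with the outcome series.", call. = FALSE)
  }
  conf <- confounders$matrix[keep, , drop = FALSE]
  cb <- crossbasis
  attr(cb, "spec") <- NULL; attr(cb, "rows_dropped") <- NULL
  X <- cbind(cb, conf)

  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- colnames(cbind(`(Intercept)` = 1, X))[qrX$pivot[-seq_len(qrX$rank)]]
    stop(sprintf("Rank-deficient design; collinear column(s): %s.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  df <- data.frame(y = y[keep])
  fit <- stats::glm(y ~ X, family = stats::quasipoisson(link = "log"),
                    data = df,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    warning("IRLS did not converge within 100 iterations.", call. = FALSE)
  }

  p_cb <- ncol(cb)
  idx_cb <- 1L + seq_len(p_cb)  # after the intercept
  sm <- summary(fit)
  dispersion <- sm$dispersion   # Pearson chi^2 / (n - p)
  V <- stats::vcov(fit)         # already dispersion-scaled for quasipoisson
  coefs <- stats::coef(fit)

  eta_hat <- unname(coefs[idx_cb])
  vcov_eta <- unname(V[idx_cb, idx_cb, drop = FALSE])
  structure(
    list(eta_hat = eta_hat,
         vcov_eta = vcov_eta,
         gamma_hat = coefs[-idx_cb],
         dispersion = dispersion,
         converged = fit$converged,
         n_obs = length(keep),
         fitted = unname(stats::fitted(fit)),
         glm = fit),
    class = "qp_fit"
  )
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf("<qp_fit> %d obs, %d cross-basis coefficients, dispersion %.3f%s\n",
              x$n_obs, length(x$eta_hat), x$dispersion,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
glance.qp_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_crossbasis = length(x$eta_hat),
    dispersion = x$dispersion,
    converged = x$converged,
    deviance = x$glm$deviance,
    null.deviance = x$glm$null.deviance
  )
}

#' Fit the temperature-mortality curve from a daily time series
#'
#' One-stop pipeline: builds the temperature basis with interior knots at
#' the requested percentiles of the observed exposure metric, assembles the
#' cross-basis (moving average by default), adds the day-of-week and
#' seasonal confounders, fits the quasi-Poisson model and reduces the
#' coefficients to the lag-cumulated curve.
#'
#' @param data A data frame with columns `date`, `deaths`, `temperature`.
#' @param knot_percentiles Interior knot placement for the quadratic
#'   B-spline temperature basis, as percentiles of the exposure metric
#'   (default 10, 75, 90).
#' @param ma_window Moving-average window in days for the temperature
#'   metric (default 1 = current-day temperature). Ignored when `lag_spline`
#'   is supplied.
#' @param lag_spline Optional [spline_spec()] for a genuine bidimensional
#'   cross-basis; with `max_lag` it replaces the moving-average metric.
#' @param max_lag Maximum lag when `lag_spline` is supplied.
#' @param df_per_year Time-spline degrees of freedom per year (default 8).
#' @param grid_step Temperature grid resolution for argmin searches
#'   (default 0.1 degrees C).
#' @return A list of class `mmt_fit` with elements `fit` (the
#'   [fit_quasipoisson()] result), `reduced` (the [reduced_fit()]), `spec`
#'   (the [crossbasis_spec()]), and `exposure` (the exposure metric series
#'   after dropping incomplete-lag days).
#' @examples
#' sc <- scenario_spec("u", n_years = 2)
#' d <- generate_dataset(sc, seed = 1)
#' f <- fit_mmt_model(d, ma_window = sc$ma_window)
#' argmin_mmt(f$reduced)
#' @export
fit_mmt_model <- function(data, knot_percentiles = c(10, 75, 90),
                          ma_window = 1L, lag_spline = NULL, max_lag = NULL,
                          df_per_year = 8, grid_step = 0.1) {
  stopifnot(is.data.frame(data))
  temps <- data$temperature
  if (is.null(temps)) stop("`data` must have a `temperature` column.", call. = FALSE)

  if (is.null(lag_spline)) {
    L <- as.integer(ma_window) - 1L
    metric <- .trailing_mean(temps, L + 1L)
    metric_obs <- metric[(L + 1L):length(metric)]
    lag <- "ma"
  } else {
    if (is.null(max_lag)) stop("Supply `max_lag` with `lag_spline`.", call. = FALSE)
    L <- as.integer(max_lag)
    metric_obs <- temps[(L + 1L):length(temps)]
    lag <- lag_spline
  }

  knots <- unname(stats::quantile(metric_obs, knot_percentiles / 100, type = 7))
  tspec <- spline_spec("quadratic_bspline", internal_knots = knots,
                       boundary_knots = range(metric_obs), intercept = FALSE)
  cbspec <- crossbasis_spec(tspec, lag_spline = lag, max_lag = L)
  cb <- build_crossbasis(temps, cbspec)
  conf <- build_confounders(data$date, df_per_year = df_per_year)
  fit <- fit_quasipoisson(data, cb, conf)
  reduced <- reduce_coefficients(fit$eta_hat, fit$vcov_eta, cbspec,
                                 temps = metric_obs, grid_step = grid_step)
  structure(list(fit = fit, reduced = reduced, spec = cbspec,
                 exposure = metric_obs),
            class = "mmt_fit")
}

#' @export
print.mmt_fit <- function(x, ...) {
  print(x$fit); print(x$reduced)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
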