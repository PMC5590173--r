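#' Lag-cumulated log relative risk curve
#'
#' Evaluates the unreferenced log relative-risk curve Q_x beta over a
#' temperature grid: the lag-cumulated association implied by a
#' [reduced_fit()]. The curve is only defined over the observed temperature
#' range; requesting values outside it is an error.
#'
#' @param fit A [reduced_fit()].
#' @param grid Temperatures at which to evaluate (defaults to the fit's
#'   grid).
#' @return Numeric vector of log relative risks (unreferenced: only
#'   differences between temperatures are meaningful).
#' @export
log_rr_curve <- function(fit, grid = fit$temp_grid) {
  stopifnot(inherits(fit, "reduced_fit"))
  Q <- eval_spline(grid, fit$temp_spline)
  drop(Q %*% fit$beta)
}

#' Argmin point estimate of the minimum mortality temperature
#'
#' The temperature minimizing the fitted lag-cumulated curve Q_x beta over
#' a finite grid spanning the observed range. Without a constraint this is
#' the unconstrained estimator (the minimizer may sit on the boundary of
#' the observed range); with `constraint = c(1, 99)` the search is
#' restricted to grid points between the 1st and 99th observed temperature
#' percentiles, the usual guard against boundary solutions. Ties are broken
#' toward the lowest temperature.
#'
#' @param fit A [reduced_fit()].
#' @param constraint `NULL` for the unconstrained argmin, or a length-2
#'   percentile pair (e.g. `c(1, 99)`) restricting the search.
#' @return A single temperature (degrees C).
#' @export
argmin_mmt <- function(fit, constraint = NULL) {
  stopifnot(inherits(fit, "reduced_fit"))
  grid <- fit$temp_grid
  if (!is.null(constraint)) {
    stopifnot(length(constraint) == 2L, constraint[1] < constraint[2])
    bounds <- observed_percentiles(fit, constraint)
    keep <- grid >= bounds[1] & grid <= bounds[2]
    if (!any(keep)) stop("Constraint excludes the whole grid.", call. = FALSE)
    grid <- grid[keep]
  }
  curve <- log_rr_curve(fit, grid)
  grid[which.min(curve)]
}

#' Uniform prior support for the minimum mortality temperature
#'
#' A plausible range (alpha_1, alpha_2) for the MMT under a uniform prior,
#' given either in absolute degrees C or as percentiles of the observed
#' temperature distribution (resolved per dataset).
#'
#' @param lower,upper Support endpoints, `lower < upper`.
#' @param mode `"percentile"` (default) or `"absolute"`.
#' @return An object of class `prior_support`.
#' @examples
#' prior_support(1, 99)              # minimally informative
#' prior_support(18, 26, "absolute") # absolute degrees C
#' @export
prior_support <- function(lower, upper, mode = c("percentile", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L, lower < upper)
  if (mode == "percentile" && (lower < 0 || upper > 100)) {
    stop("Percentile supports must lie in [0, 100].", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, mode = mode),
            class = "prior_support")
}

#' @export
print.prior_support <- function(x, ...) {
  cat(sprintf("<prior_support> Uniform(%g, %g) [%s]\n", x$lower, x$upper, x$mode))
  invisible(x)
}

# Resolve a prior support to absolute temperatures for a given fit.
.resolve_support <- function(prior, fit) {
  if (prior$mode == "percentile") {
    unname(observed_percentiles(fit, c(prior$lower, prior$upper)))
  } else {
    c(prior$lower, prior$upper)
  }
}

# Symmetric PSD square root with eigenvalue clipping: covariances arriving
# through the reduction can be numerically indefinite at round-off level.
.mvn_factor <- function(vcov) {
  eg <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE)
  vals <- eg$values
  if (min(vals) < -1e-8 * max(abs(vals), 1e-12)) {
    stop("Covariance is not positive semidefinite within tolerance.",
         call. = FALSE)
  }
  eg$vectors %*% diag(sqrt(pmax(vals, 0)), length(vals))
}

#' Monte Carlo sample of the minimum mortality temperature
#'
#' Draws the empirical MMT distribution by parametric bootstrap: coefficient
#' draws beta_(i) ~ MVN(beta, V(beta)) are converted to MMT draws
#' theta_(i) = argmin_x Q_x beta_(i) over the temperature grid. Without a
#' prior this is the unrestricted sampler (method `"empirical1"`). With a
#' `prior_support` the same proposal stream is filtered by rejection,
#' keeping only draws whose argmin falls inside the uniform prior support
#' (method `"empirical2"`), until `n_sim` draws are accepted or the
#' proposal budget (`budget_factor * n_sim` proposals) is exhausted. An
#' acceptance rate below 0.5\% after the full budget is an error: the
#' support is then incompatible with the data.
#'
#' The proposal stream is a deterministic function of `seed`, so runs with
#' and without a prior (same seed) share proposals: the restricted sample
#' is exactly the unrestricted sample intersected with the support.
#'
#' @param fit A [reduced_fit()].
#' @param n_sim Number of Monte Carlo draws to retain (default 5000).
#' @param prior Optional [prior_support()].
#' @param seed Optional integer seed for the proposal stream.
#' @param point_rule `"mean"` (default) or `"median"` for the point
#'   estimate.
#' @param percentile_pair Interval percentiles, default `c(2.5, 97.5)`;
#'   use `c(0, 95)` for highly right-skewed MMT distributions.
#' @param budget_factor Proposal budget multiplier for rejection sampling
#'   (default 100).
#' @return An object of class `mmt_result`; see [summarize_mmt()] for the
#'   summary fields. Carries the paired coefficient draws (`beta_draws`,
#'   one column per retained draw) needed to propagate MMT uncertainty
#'   into relative risks.
#' @export
sample_mmt <- function(fit, n_sim = 5000L, prior = NULL, seed = NULL,
                       point_rule = c("mean", "median"),
                       percentile_pair = c(2.5, 97.5),
                       budget_factor = 100L) {
  stopifnot(inherits(fit, "reduced_fit"), n_sim >= 1L)
  n_sim <- as.integer(n_sim)
  point_rule <- match.arg(point_rule)
  if (!is.null(prior)) {
    stopifnot(inherits(prior, "prior_support"))
    support <- .resolve_support(prior, fit)
    if (support[2] < min(fit$temp_grid) || support[1] > max(fit$temp_grid)) {
      stop("Prior support does not overlap the temperature grid.", call. = FALSE)
    }
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  v_x <- length(fit$beta)
  E <- .mvn_factor(fit$vcov)
  Qg <- eval_spline(fit$temp_grid, fit$temp_spline)

  theta <- numeric(0)
  beta_keep <- matrix(numeric(), nrow = v_x, ncol = 0)
  n_proposed <- 0L
  budget <- as.integer(budget_factor) * n_sim

  while (length(theta) < n_sim && n_proposed < budget) {
    block <- min(n_sim, budget - n_proposed)
    Z <- matrix(stats::rnorm(v_x * block), nrow = v_x)
    B <- fit$beta + E %*% Z                     # v_x x block
    curves <- Qg %*% B                          # n_grid x block
    idx <- max.col(-t(curves), ties.method = "first")  # lowest-temperature tie-break
    th <- fit$temp_grid[idx]
    if (is.null(prior)) {
      keep <- rep(TRUE, block)
    } else {
      keep <- th >= support[1] & th <= support[2]
    }
    need <- n_sim - length(theta)
    if (sum(keep) > need) {
      # stop at the proposal that yields the n_sim-th acceptance, so the
      # acceptance bookkeeping reflects the stream actually consumed
      last <- which(cumsum(keep) == need)[1L]
      keep[seq_along(keep) > last] <- FALSE
      block <- last
    }
    n_proposed <- n_proposed + block
    if (any(keep)) {
      theta <- c(theta, th[keep])
      beta_keep <- cbind(beta_keep, B[, keep, drop = FALSE])
    }
  }
  n_accepted <- length(theta)
  if (!is.null(prior) && n_accepted < n_sim) {
    rate <- n_accepted / n_proposed
    if (rate < 0.005) {
      stop(sprintf(
        "Prior support [%.2f, %.2f] is incompatible with the data: acceptance rate %.3f%% after %d proposals.",
        support[1], support[2], 100 * rate, n_proposed), call. = FALSE)
    }
    warning(sprintf("Proposal budget exhausted: %d of %d draws accepted.",
                    n_accepted, n_sim), call. = FALSE)
  }
  if (n_accepted == 0L) stop("No MMT draws retained.", call. = FALSE)

  s <- summarize_mmt(theta, point_rule = point_rule,
                     percentile_pair = percentile_pair)
  structure(
    list(method = if (is.null(prior)) "empirical1" else "empirical2",
         point = s$point,
         interval = s$interval,
         samples = theta,
         beta_draws = beta_keep,
         n_proposed = n_proposed,
         n_accepted = n_accepted,
         percentile_pair = s$percentile_pair,
         point_rule = point_rule,
         skewness = s$skewness,
         prior = prior,
         fit = fit),
    class = "mmt_result"
  )
}

#' Summarize an empirical MMT distribution
#'
#' Point and interval estimates from a Monte Carlo MMT sample: the point is
#' the empirical mean (or median) and the interval the empirical
#' percentiles, computed by linear interpolation between order statistics.
#' The default pair (2.5, 97.5) gives a 95\% interval; the skew-adjusted
#' pair (0, 95) is appropriate for highly right-skewed distributions (such
#' as sector-shaped associations with the minimum near the cold boundary).
#' Sample skewness is reported so the caller can judge; no automatic switch
#' is applied.
#'
#' @param samples Numeric vector of MMT draws (>= 2 for an interval).
#' @param point_rule `"mean"` or `"median"`.
#' @param percentile_pair Length-2 percentiles in \[0, 100\].
#' @return A list with `point`, `interval` (length 2), `percentile_pair`,
#'   `skewness`, `n`.
#' @export
summarize_mmt <- function(samples, point_rule = c("mean", "median"),
                          percentile_pair = c(2.5, 97.5)) {
  point_rule <- match.arg(point_rule)
  samples <- as.numeric(samples)
  if (!length(samples)) stop("Empty sample.", call. = FALSE)
  stopifnot(length(percentile_pair) == 2L,
            percentile_pair[1] < percentile_pair[2],
            all(percentile_pair >= 0), all(percentile_pair <= 100))
  point <- if (point_rule == "mean") mean(samples) else stats::median(samples)
  interval <- if (length(samples) >= 2L) {
    unname(stats::quantile(samples, percentile_pair / 100, type = 7))
  } else {
    stop("Need at least 2 samples for an interval.", call. = FALSE)
  }
  m <- mean(samples); s <- stats::sd(samples)
  skew <- if (s > 0) mean((samples - m)^3) / s^3 else 0
  list(point = point, interval = interval,
       percentile_pair = percentile_pair, skewness = skew,
       n = length(samples))
}

#' Re-summarize an MMT result with a different percentile pair or rule
#'
#' @param result An [sample_mmt()] result.
#' @param percentile_pair New interval percentiles.
#' @param point_rule New point rule (defaults to the original).
#' @return The updated `mmt_result`.
#' @export
resummarize_mmt <- function(result, percentile_pair = result$percentile_pair,
                            point_rule = result$point_rule) {
  stopifnot(inherits(result, "mmt_result"))
  s <- summarize_mmt(result$samples, point_rule = point_rule,
                     percentile_pair = percentile_pair)
  result$point <- s$point
  result$interval <- s$interval
  result$percentile_pair <- s$percentile_pair
  result$point_rule <- point_rule
  result
}

#' @export
print.mmt_result <- function(x, ...) {
  cat(sprintf("<mmt_result> %s: MMT %.2f degC, %g%%-%g%% interval [%.2f, %.2f]\n",
              x$method, x$point, x$percentile_pair[1], x$percentile_pair[2],
              x$interval[1], x$interval[2]))
  cat(sprintf("  %d draws retained of %d proposed (skewness %.2f)\n",
              x$n_accepted, x$n_proposed, x$skewness))
  invisible(x)
}

#' @export
tidy.mmt_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    estimate = x$point,
    conf.low = x$interval[1],
    conf.high = x$interval[2],
    percentile_low = x$percentile_pair[1],
    percentile_high = x$percentile_pair[2],
    n_accepted = x$n_accepted,
    n_proposed = x$n_proposed,
    skewness = x$skewness
  )
}

#' @export
glance.mmt_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_accepted = x$n_accepted,
    n_proposed = x$n_proposed,
    acceptance_rate = x$n_accepted / x$n_proposed,
    point_rule = x$point_rule
  )
}
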