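#' Relative risk at a temperature, MMT uncertainty propagated
#'
#' For each retained Monte Carlo draw i the log relative risk comparing
#' temperature `x` against that draw's own MMT is
#' \deqn{\zeta_{(i)} = (Q_x - Q_{\theta_{(i)}})\,\beta_{(i)},\qquad
#'       RR_{(i)} = \exp(\zeta_{(i)}),}
#' using the coefficient draw beta_(i) paired with its argmin theta_(i).
#' The empirical distribution of RR_(i) is summarized like the MMT
#' distribution: empirical mean (or median) point estimate and percentile
#' interval.
#'
#' @param fit A [reduced_fit()] (the fit the draws came from).
#' @param mmt_samples An [sample_mmt()] result carrying paired
#'   `beta_draws`.
#' @param x Comparison temperature (degrees C, inside the observed range).
#' @param point_rule `"mean"` (default) or `"median"`.
#' @param percentile_pair Interval percentiles, default `c(2.5, 97.5)`.
#' @return An object of class `rr_result`.
#' @export
rr_empirical <- function(fit, mmt_samples, x,
                         point_rule = c("mean", "median"),
                         percentile_pair = c(2.5, 97.5)) {
  stopifnot(inherits(fit, "reduced_fit"), inherits(mmt_samples, "mmt_result"),
            length(x) == 1L)
  point_rule <- match.arg(point_rule)
  B <- mmt_samples$beta_draws
  theta <- mmt_samples$samples
  if (is.null(B) || ncol(B) != length(theta)) {
    stop("MMT draws are not paired with their coefficient draws.", call. = FALSE)
  }
  Qx <- eval_spline(x, fit$temp_spline)
  Qtheta <- eval_spline(theta, fit$temp_spline)
  # log RR per draw: (Q_x - Q_theta_i) beta_i
  zeta <- as.numeric(Qx %*% B) - colSums(t(Qtheta) * B)
  rr <- exp(zeta)
  s <- summarize_mmt(rr, point_rule = point_rule,
                     percentile_pair = percentile_pair)
  structure(
    list(comparison_temperature = x,
         reference = "empirical",
         point = s$point,
         interval = s$interval,
         samples = rr,
         percentile_pair = s$percentile_pair,
         method = mmt_samples$method),
    class = "rr_result"
  )
}

#' Relative risk against a fixed MMT reference
#'
#' The conventional estimate ignoring MMT uncertainty: the MMT point
#' estimate m is treated as a known reference, the log relative risk is the
#' linear contrast (Q_x - Q_m) beta-hat, and the 95\% confidence interval
#' follows from the normal approximation with delta-method variance
#' (Q_x - Q_m) V(beta) (Q_x - Q_m)'.
#'
#' @param fit A [reduced_fit()].
#' @param mmt_point Reference temperature (the MMT point estimate).
#' @param x Comparison temperature.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `rr_result`.
#' @export
rr_fixed <- function(fit, mmt_point, x, conf_level = 0.95) {
  stopifnot(inherits(fit, "reduced_fit"), length(x) == 1L,
            length(mmt_point) == 1L)
  d <- eval_spline(x, fit$temp_spline) - eval_spline(mmt_point, fit$temp_spline)
  log_rr <- drop(d %*% fit$beta)
  v <- drop(d %*% fit$vcov %*% t(d))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(comparison_temperature = x,
         reference = mmt_point,
         point = exp(log_rr),
         interval = exp(log_rr + c(-1, 1) * z * sqrt(max(v, 0))),
         samples = NULL,
         conf_level = conf_level,
         method = "fixed"),
    class = "rr_result"
  )
}

#' Cold- and heat-related relative risks
#'
#' The two summaries of epidemiological interest: the relative risk
#' comparing the 1st percentile of the observed temperature distribution
#' against the MMT (cold-related), and the 99th percentile against the MMT
#' (heat-related). When `mmt` is an [sample_mmt()] result the MMT
#' uncertainty is propagated ([rr_empirical()]); when it is a single
#' temperature (an argmin point estimate) the fixed-reference
#' normal-approximation interval is used ([rr_fixed()]).
#'
#' @param fit A [reduced_fit()].
#' @param mmt Either an `mmt_result` or a single reference temperature.
#' @param percentiles Cold/heat comparison percentiles, default `c(1, 99)`.
#' @param ... Passed to [rr_empirical()] or [rr_fixed()].
#' @return A list with elements `cold` and `heat`, each an `rr_result`.
#' @export
cold_heat_rr <- function(fit, mmt, percentiles = c(1, 99), ...) {
  stopifnot(inherits(fit, "reduced_fit"))
  refs <- observed_percentiles(fit, percentiles)
  one <- function(x) {
    if (inherits(mmt, "mmt_result")) rr_empirical(fit, mmt, x, ...)
    else rr_fixed(fit, mmt, x, ...)
  }
  list(cold = one(unname(refs[1])), heat = one(unname(refs[2])))
}

#' @export
print.rr_result <- function(x, ...) {
  ref <- if (identical(x$reference, "empirical")) "empirical MMT" else
    sprintf("MMT %.2f degC", x$reference)
  cat(sprintf("<rr_result> RR at %.2f degC vs %s: %.4f [%.4f, %.4f]\n",
              x$comparison_temperature, ref, x$point,
              x$interval[1], x$interval[2]))
  invisible(x)
}

#' @export
tidy.rr_result <- function(x, ...) {
  tibble::tibble(
    comparison_temperature = x$comparison_temperature,
    reference = if (identical(x$reference, "empirical")) NA_real_ else x$reference,
    reference_type = if (identical(x$reference, "empirical")) "empirical" else "fixed",
    estimate = x$point,
    conf.low = x$interval[1],
    conf.high = x$interval[2]
  )
}
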