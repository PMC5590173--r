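#' @keywords internal
#' @importFrom rlang .data
#' @importFrom dplyr %>%
"_PACKAGE"

#' Plot the lag-cumulated temperature-mortality curve
#'
#' Relative-risk curve referenced to its grid minimum, with a pointwise
#' 95\% normal-approximation band from V(beta).
#'
#' @param object A [reduced_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reduced_fit <- function(object, ...) {
  grid <- object$temp_grid
  Q <- eval_spline(grid, object$temp_spline)
  curve <- drop(Q %*% object$beta)
  ref_idx <- which.min(curve)
  D <- sweep(Q, 2, Q[ref_idx, ])     # contrasts against the curve minimum
  se <- sqrt(pmax(rowSums((D %*% object$vcov) * D), 0))
  df <- tibble::tibble(
    temperature = grid,
    rr = exp(curve - curve[ref_idx]),
    lo = exp(curve - curve[ref_idx] - 1.96 * se),
    hi = exp(curve - curve[ref_idx] + 1.96 * se)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = grid[ref_idx], linetype = "dotted") +
    ggplot2::labs(x = "Temperature (°C)", y = "Relative risk",
                  title = "Lag-cumulated temperature-mortality association") +
    ggplot2::theme_minimal()
}

#' Plot an empirical MMT distribution
#'
#' Histogram of the Monte Carlo MMT draws with the point estimate and the
#' percentile interval marked.
#'
#' @param object An [sample_mmt()] result.
#' @param binwidth Histogram bin width in degC (default the fit grid step).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mmt_result <- function(object, binwidth = NULL, ...) {
  binwidth <- binwidth %||% (object$fit$grid_step * 5)
  df <- tibble::tibble(theta = object$samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$point, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$interval,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Minimum mortality temperature (°C)", y = "Draws",
                  title = sprintf("Empirical MMT distribution (%s)", object$method),
                  subtitle = sprintf("point %.2f, %g%%-%g%% interval [%.2f, %.2f]",
                                     object$point, object$percentile_pair[1],
                                     object$percentile_pair[2],
                                     object$interval[1], object$interval[2])) +
    ggplot2::theme_minimal()
}

#' Plot simulation-study metrics
#'
#' Bar panels of bias, RMSE, coverage and mean interval length per method
#' for one quantity of a study metric table.
#'
#' @param metrics A [study_metrics()] table.
#' @param quantity Which quantity to display (default `"mmt"`).
#' @return A ggplot object.
#' @export
plot_study_metrics <- function(metrics, quantity = "mmt") {
  df <- metrics |>
    dplyr::filter(.data$quantity == !!quantity) |>
    tidyr::pivot_longer(c("bias", "rmse", "coverage_pct", "mean_length"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Estimator performance: %s", quantity)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
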