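#' Cross-basis specification for a distributed lag nonlinear model
#'
#' Couples a temperature basis with a lag structure. Three lag structures are
#' supported:
#' \describe{
#'   \item{a `spline_spec`}{a genuine bidimensional cross-basis, with
#'     `v_l = basis_dim(lag_spline)` lag basis functions evaluated at lags
#'     0..L;}
#'   \item{`"ma"`}{the moving-average special case: the temperature basis is
#'     applied to the (L+1)-day trailing moving average, `v_l = 1`, and the
#'     fitted coefficients coincide with the lag-cumulated coefficients;}
#'   \item{`"constant"`}{a single lag basis function identically equal to 1
#'     (unweighted sum over lags), `v_l = 1`.}
#' }
#'
#' @param temp_spline [spline_spec()] for the temperature axis.
#' @param lag_spline A [spline_spec()] on the lag axis, or `"ma"`, or
#'   `"constant"`.
#' @param max_lag Maximum lag L in days (>= 0).
#' @return An object of class `crossbasis_spec` with fields `temp_spline`,
#'   `lag_spline`, `max_lag`, `v_x`, `v_l`.
#' @examples
#' ts <- spline_spec("quadratic_bspline", c(10, 22.5, 27), c(0, 30))
#' crossbasis_spec(ts, lag_spline = "ma", max_lag = 2)
#' @export
crossbasis_spec <- function(temp_spline, lag_spline = "ma", max_lag = 0L) {
  stopifnot(inherits(temp_spline, "spline_spec"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("`max_lag` must be >= 0.", call. = FALSE)
  if (is.character(lag_spline)) {
    lag_spline <- match.arg(lag_spline, c("ma", "constant"))
    v_l <- 1L
  } else {
    stopifnot(inherits(lag_spline, "spline_spec"))
    if (max_lag < 1L) {
      stop("A spline lag basis requires `max_lag` >= 1.", call. = FALSE)
    }
    v_l <- basis_dim(lag_spline)
  }
  structure(
    list(temp_spline = temp_spline, lag_spline = lag_spline,
         max_lag = max_lag, v_x = basis_dim(temp_spline), v_l = v_l),
    class = "crossbasis_spec"
  )
}

#' @export
print.crossbasis_spec <- function(x, ...) {
  lag <- if (is.character(x$lag_spline)) x$lag_spline else x$lag_spline$family
  cat(sprintf("<crossbasis_spec> v_x = %d, v_l = %d, max lag %d (%s lag structure)\n",
              x$v_x, x$v_l, x$max_lag, lag))
  invisible(x)
}

#' Lag basis matrix C
#'
#' The (L+1) x v_l matrix of lag basis functions evaluated at the integer
#' lags 0..L; column k holds psi_k(0), ..., psi_k(L). For the
#' moving-average structure this is the single column of window weights
#' 1/(L+1); for `"constant"` it is a column of ones.
#'
#' @param spec A [crossbasis_spec()].
#' @return Numeric matrix with `max_lag + 1` rows and `v_l` columns.
#' @export
lag_basis_matrix <- function(spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  L <- spec$max_lag
  if (is.character(spec$lag_spline)) {
    if (spec$lag_spline == "ma") {
      matrix(1 / (L + 1), nrow = L + 1L, ncol = 1L)
    } else {
      matrix(1, nrow = L + 1L, ncol = 1L)
    }
  } else {
    unname(eval_spline(0:L, spec$lag_spline))
  }
}

#' Build the cross-basis design matrix
#'
#' Assembles the DLNM design columns from a daily temperature series. Row t
#' (for t = L+1, ..., N in the original series; the first L days lack a
#' complete lag history and are dropped) and column (j, k) hold
#' \deqn{\sum_{l=0}^{L} \phi_j(x_{t-l})\, \psi_k(l),}
#' the tensor-product term coupling temperature basis function j with lag
#' basis function k. Columns are ordered with the temperature index j
#' varying fastest (column index `(k-1) v_x + j`), matching the Kronecker
#' structure used by [reduce_coefficients()].
#'
#' Under the `"ma"` lag structure the matrix is instead the temperature
#' basis evaluated at the (L+1)-day trailing moving average, the standard
#' moving-average special case of the DLNM.
#'
#' @param temps Numeric vector: the daily mean temperature series.
#' @param spec A [crossbasis_spec()].
#' @return Numeric matrix with `length(temps) - max_lag` rows and
#'   `v_x * v_l` columns; attributes `"spec"` and `"rows_dropped"` record
#'   the specification and the L leading days removed.
#' @export
build_crossbasis <- function(temps, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  temps <- as.numeric(temps)
  L <- spec$max_lag
  n <- length(temps)
  if (n <= L) {
    stop(sprintf("Series of length %d cannot support max lag %d; need at least L + 1 days.",
                 n, L), call. = FALSE)
  }
  keep <- (L + 1L):n

  if (is.character(spec$lag_spline) && spec$lag_spline == "ma") {
    xma <- .trailing_mean(temps, L + 1L)[keep]
    cb <- eval_spline(xma, spec$temp_spline)
    colnames(cb) <- paste0("cb_", seq_len(ncol(cb)), "_1")
  } else {
    C <- lag_basis_matrix(spec)
    v_x <- spec$v_x; v_l <- spec$v_l
    cb <- matrix(0, length(keep), v_x * v_l)
    for (l in 0:L) {
      phi <- eval_spline(temps[keep - l], spec$temp_spline)
      # add phi_j(x_{t-l}) * psi_k(l) into column (k-1)*v_x + j
      cb <- cb + phi[, rep.int(seq_len(v_x), v_l), drop = FALSE] *
        rep(C[l + 1L, ], each = v_x)[col(cb)]
    }
    colnames(cb) <- paste0("cb_", rep(seq_len(v_x), v_l), "_",
                           rep(seq_len(v_l), each = v_x))
  }
  attr(cb, "spec") <- spec
  attr(cb, "rows_dropped") <- L
  cb
}

.trailing_mean <- function(x, width) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  out <- rep(NA_real_, n)
  idx <- width:n
  out[idx] <- (cs[idx + 1L] - cs[idx + 1L - width]) / width
  out
}

#' Reduce cross-basis coefficients to lag-cumulated coefficients
#'
#' Collapses the cross-basis coefficient vector eta (dimension v_x * v_l)
#' to the coefficients beta of the lag-cumulated temperature-mortality
#' curve through the linear map beta = M eta with
#' M = (1' C) \%x\% I_{v_x}, where C is the lag basis matrix
#' ([lag_basis_matrix()]). The covariance transforms as M V(eta) M'. The
#' coefficient ordering must match [build_crossbasis()] (temperature index
#' fastest). For the moving-average structure M is the identity: the fitted
#' coefficients already describe the cumulated curve.
#'
#' @param eta Numeric vector of cross-basis coefficients, length v_x * v_l.
#' @param vcov_eta Covariance matrix of `eta`.
#' @param spec The [crossbasis_spec()] used to build the design.
#' @param temps Observed exposure series (the temperature metric actually
#'   entering the basis, e.g. the moving average under `"ma"`); used to set
#'   the evaluation grid and observed percentiles of the result.
#' @param grid_step Grid resolution in degrees C for downstream argmin
#'   computations (default 0.1).
#' @return A [reduced_fit()] object.
#' @export
reduce_coefficients <- function(eta, vcov_eta, spec, temps,
                                grid_step = 0.1) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  eta <- as.numeric(eta)
  vcov_eta <- as.matrix(vcov_eta)
  p <- spec$v_x * spec$v_l
  if (length(eta) != p) {
    stop(sprintf("`eta` has length %d but the cross-basis has dimension %d.",
                 length(eta), p), call. = FALSE)
  }
  if (!all(dim(vcov_eta) == c(p, p))) {
    stop(sprintf("`vcov_eta` must be %d x %d.", p, p), call. = FALSE)
  }
  M <- reduction_matrix(spec)
  reduced_fit(beta = drop(M %*% eta),
              vcov = M %*% vcov_eta %*% t(M),
              temp_spline = spec$temp_spline,
              temps = temps,
              grid_step = grid_step)
}

#' Reduction matrix M = (1'C) \%x\% I
#'
#' @param spec A [crossbasis_spec()].
#' @return A `v_x` x `v_x * v_l` matrix; the identity for the
#'   moving-average structure.
#' @export
reduction_matrix <- function(spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  if (is.character(spec$lag_spline) && spec$lag_spline == "ma") {
    return(diag(spec$v_x))
  }
  C <- lag_basis_matrix(spec)
  kronecker(matrix(colSums(C), nrow = 1L), diag(spec$v_x))
}

#' Lag-cumulated fit: coefficients of the temperature-mortality curve
#'
#' The substrate of all MMT and relative-risk inference: the lag-cumulated
#' coefficient vector beta, its covariance V(beta), the temperature basis
#' they refer to, the evaluation grid spanning the observed exposure range,
#' and the observed series itself (for percentile-based constraints, prior
#' supports, and cold/heat reference temperatures).
#'
#' @param beta Numeric vector of length `basis_dim(temp_spline)`.
#' @param vcov Symmetric positive semidefinite covariance of `beta`.
#' @param temp_spline [spline_spec()] for the temperature basis.
#' @param temps Observed exposure series (degrees C).
#' @param grid_step Evaluation grid resolution, degrees C.
#' @return An object of class `reduced_fit` with fields `beta`, `vcov`,
#'   `temp_spline`, `temp_grid`, `temps`, `grid_step`.
#' @export
reduced_fit <- function(beta, vcov, temp_spline, temps, grid_step = 0.1) {
  stopifnot(inherits(temp_spline, "spline_spec"))
  beta <- as.numeric(beta)
  vcov <- unname(as.matrix(vcov))
  v_x <- basis_dim(temp_spline)
  if (length(beta) != v_x) {
    stop(sprintf("`beta` has length %d but the basis has dimension %d.",
                 length(beta), v_x), call. = FALSE)
  }
  if (!all(dim(vcov) == c(v_x, v_x))) stop("`vcov` non-conformable.", call. = FALSE)
  if (max(abs(vcov - t(vcov))) > 1e-8 * max(1, max(abs(vcov)))) {
    stop("`vcov` is not symmetric.", call. = FALSE)
  }
  vcov <- (vcov + t(vcov)) / 2
  ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1e-12)) {
    stop("`vcov` is not positive semidefinite within tolerance.", call. = FALSE)
  }
  temps <- as.numeric(temps)
  temps <- temps[is.finite(temps)]
  if (!length(temps)) stop("`temps` must contain finite values.", call. = FALSE)
  rng <- range(temps)
  grid <- seq(rng[1], rng[2], by = grid_step)
  if (grid[length(grid)] < rng[2]) grid <- c(grid, rng[2])
  structure(
    list(beta = beta, vcov = vcov, temp_spline = temp_spline,
         temp_grid = grid, temps = temps, grid_step = grid_step),
    class = "reduced_fit"
  )
}

#' @export
print.reduced_fit <- function(x, ...) {
  cat(sprintf("<reduced_fit> %d coefficients on [%.2f, %.2f] degC (grid step %g)\n",
              length(x$beta), min(x$temp_grid), max(x$temp_grid), x$grid_step))
  invisible(x)
}

#' Observed temperature percentiles of a reduced fit
#'
#' Percentiles of the observed exposure series, computed by linear
#' interpolation between order statistics (the same definition used for the
#' constrained argmin, prior supports in percentile mode, and the cold/heat
#' reference temperatures).
#'
#' @param fit A [reduced_fit()].
#' @param probs Percentiles in \[0, 100\].
#' @return Named numeric vector of temperatures.
#' @export
observed_percentiles <- function(fit, probs = c(1, 99)) {
  stopifnot(inherits(fit, "reduced_fit"))
  if (any(probs < 0 | probs > 100)) {
    stop("Percentiles must be in [0, 100].", call. = FALSE)
  }
  stats::quantile(fit$temps, probs / 100, type = 7, names = TRUE)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.reduced_fit <- function(x, ...) {
  tibble::tibble(
    term = paste0("b", seq_along(x$beta)),
    estimate = x$beta,
    std.error = sqrt(pmax(diag(x$vcov), 0))
  )
}

#' @export
glance.reduced_fit <- function(x, ...) {
  tibble::tibble(
    n_coef = length(x$beta),
    temp_min = min(x$temp_grid),
    temp_max = max(x$temp_grid),
    grid_step = x$grid_step,
    n_grid = length(x$temp_grid)
  )
}
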