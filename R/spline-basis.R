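#' Spline basis specification
#'
#' Describes a one-dimensional spline basis used either on the temperature
#' axis (exposure-response) or on the lag axis of a cross-basis. Two families
#' are supported: quadratic B-splines (the usual choice for the
#' temperature-mortality curve, with interior knots at temperature
#' percentiles) and natural cubic splines (linear beyond the boundary knots;
#' the usual choice for the lag structure and for seasonality control).
#'
#' @param family `"quadratic_bspline"` or `"natural_cubic"`.
#' @param internal_knots Strictly increasing numeric vector of interior knots,
#'   in degrees Celsius (temperature axis) or days (lag axis). May be empty.
#' @param boundary_knots Length-2 numeric vector enclosing all internal knots.
#'   For temperature bases this is normally the observed data range, so that
#'   evaluation never extrapolates.
#' @param intercept Should the basis span the constant function? Defaults to
#'   `FALSE` for temperature bases (the model has its own intercept) and is
#'   normally `TRUE` for lag bases.
#'
#' @return An object of class `spline_spec`.
#' @examples
#' spline_spec("quadratic_bspline", internal_knots = c(10, 22.5, 27),
#'             boundary_knots = c(0, 30))
#' @export
spline_spec <- function(family = c("quadratic_bspline", "natural_cubic"),
                        internal_knots = numeric(),
                        boundary_knots,
                        intercept = FALSE) {
  family <- match.arg(family)
  internal_knots <- as.numeric(internal_knots)
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L || any(!is.finite(boundary_knots)) ||
      diff(boundary_knots) <= 0) {
    stop("`boundary_knots` must be two finite, increasing values.",
         call. = FALSE)
  }
  if (length(internal_knots)) {
    if (any(!is.finite(internal_knots))) {
      stop("Internal knots must be finite.", call. = FALSE)
    }
    if (is.unsorted(internal_knots, strictly = TRUE)) {
      stop("Internal knots must be strictly increasing.", call. = FALSE)
    }
    if (min(internal_knots) <= boundary_knots[1] ||
        max(internal_knots) >= boundary_knots[2]) {
      stop("Internal knots must lie strictly inside the boundary knots.",
           call. = FALSE)
    }
  }
  out <- structure(
    list(family = family,
         internal_knots = internal_knots,
         boundary_knots = boundary_knots,
         intercept = isTRUE(intercept)),
    class = "spline_spec"
  )
  stopifnot(basis_dim(out) > 0L)
  out
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf("<spline_spec> %s, %d internal knot(s), dim %d%s\n",
              x$family, length(x$internal_knots), basis_dim(x),
              if (x$intercept) ", with intercept" else ""))
  invisible(x)
}

#' Dimension of a spline basis
#'
#' Number of basis columns produced by [eval_spline()] for a given
#' specification: for a quadratic B-spline with k internal knots this is
#' k + 3 with the intercept and k + 2 without; for a natural cubic spline,
#' k + 2 with the intercept and k + 1 without.
#'
#' @param spec A [spline_spec()].
#' @return A positive integer.
#' @export
basis_dim <- function(spec) {
  stopifnot(inherits(spec, "spline_spec"))
  k <- length(spec$internal_knots)
  full <- switch(spec$family,
                 quadratic_bspline = k + 3L,
                 natural_cubic = k + 2L)
  if (spec$intercept) full else full - 1L
}

#' Evaluate a spline basis
#'
#' Evaluates the basis described by `spec` at the points `x` and returns the
#' design matrix. Quadratic B-splines are evaluated through the B-spline
#' design (Cox-de Boor) recursion; without the intercept the first column of
#' the full basis is dropped, so that together with a model intercept the
#' spanned space is unchanged. Natural cubic splines use the standard
#' natural basis with second derivative zero at and beyond the boundary
#' knots.
#'
#' B-spline bases are only defined inside their boundary knots, and the
#' temperature-mortality curve is never evaluated outside the observed
#' temperature range, so evaluation outside the boundary is an error by
#' default (`extrapolation = "error"`). Natural cubic splines extend
#' linearly and may always be evaluated anywhere.
#'
#' @param x Numeric vector of evaluation points.
#' @param spec A [spline_spec()].
#' @param extrapolation `"error"` (default) or `"extend"`. Only consulted for
#'   the B-spline family; `"extend"` evaluates the polynomial pieces of the
#'   closest boundary interval.
#' @return A numeric matrix with `length(x)` rows and [basis_dim()] columns,
#'   with the spec attached as attribute `"spec"`.
#' @export
eval_spline <- function(x, spec, extrapolation = c("error", "extend")) {
  stopifnot(inherits(spec, "spline_spec"))
  extrapolation <- match.arg(extrapolation)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("`x` must be finite.", call. = FALSE)
  if (length(x) == 0L) {
    out <- matrix(numeric(), nrow = 0L, ncol = basis_dim(spec))
    colnames(out) <- paste0("b", seq_len(ncol(out)))
    attr(out, "spec") <- spec
    return(out)
  }
  b <- spec$boundary_knots
  tol <- 1e-8 * max(1, diff(b))

  if (spec$family == "quadratic_bspline") {
    outside <- x < b[1] - tol | x > b[2] + tol
    if (any(outside) && extrapolation == "error") {
      stop(sprintf(
        "%d value(s) outside the boundary knots [%g, %g]; B-spline bases are not evaluated outside their support.",
        sum(outside), b[1], b[2]), call. = FALSE)
    }
    aug <- c(rep(b[1], 3L), spec$internal_knots, rep(b[2], 3L))
    m <- splines::splineDesign(aug, pmin(pmax(x, b[1]), b[2]),
                               ord = 3L, outer.ok = FALSE)
    if (extrapolation == "extend" && any(outside)) {
      # re-evaluate outside points from the boundary-piece polynomials
      m[outside, ] <- .bspline_extend(x[outside], aug, ord = 3L)
    }
    if (!spec$intercept) m <- m[, -1L, drop = FALSE]
  } else {
    m <- .natural_cubic_basis(x, spec$internal_knots, b)
    if (!spec$intercept) m <- m[, -1L, drop = FALSE]
  }
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  attr(m, "spec") <- spec
  m
}

# Polynomial extension of the boundary pieces: evaluate basis and its
# derivatives at the boundary and use a Taylor expansion (exact for
# piecewise polynomials of the given order).
.bspline_extend <- function(x, aug, ord) {
  lo <- aug[1]; hi <- aug[length(aug)]
  out <- matrix(0, length(x), length(aug) - ord)
  for (side in c("lo", "hi")) {
    at <- if (side == "lo") lo else hi
    idx <- if (side == "lo") x < at else x > at
    if (!any(idx)) next
    d <- x[idx] - at
    acc <- 0
    for (k in 0:(ord - 1L)) {
      dk <- splines::splineDesign(aug, rep(at, 1L), ord = ord, derivs = k)
      acc <- acc + outer(d^k, dk[1L, ]) / factorial(k)
    }
    out[idx, ] <- acc
  }
  out
}

# Natural cubic spline basis with the constant included as column 1,
# matching splines::ns(x, knots, Boundary.knots, intercept = TRUE) up to
# the leading constant column: we build [1, ns(..., intercept = FALSE)].
# Any parameterization of the same function space is equivalent for the
# model fits, reductions and argmins computed downstream.
.natural_cubic_basis <- function(x, internal_knots, boundary) {
  n <- length(x)
  if (length(internal_knots)) {
    ns_part <- splines::ns(x, knots = internal_knots,
                           Boundary.knots = boundary, intercept = FALSE)
  } else {
    ns_part <- splines::ns(x, df = 1L, Boundary.knots = boundary,
                           intercept = FALSE)
  }
  cbind(1, unclass(ns_part)[, , drop = FALSE])
}

#' Lag knots equally spaced on the log scale
#'
#' Standard placement of interior knots for the lag dimension of a
#' cross-basis: `n_knots` values equally spaced between `log(1)` and
#' `log(max_lag)` on the log scale, exponentiated back to the lag scale.
#' Values are kept as real numbers (not rounded to whole days).
#'
#' @param max_lag Maximum lag L in days (>= 2).
#' @param n_knots Number of interior knots, default 3.
#' @return Numeric vector of length `n_knots`, strictly inside `(0, max_lag)`.
#' @export
log_lag_knots <- function(max_lag, n_knots = 3L) {
  stopifnot(max_lag >= 2, n_knots >= 1)
  exp(seq(log(1), log(max_lag), length.out = n_knots + 2L))[-c(1L, n_knots + 2L)]
}
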