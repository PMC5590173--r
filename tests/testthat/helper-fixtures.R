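# Small fixtures built in code.

# A reduced fit whose curve is exactly (x - center)^2 / scale on `range`
# (the quadratic B-spline space with intercept contains all quadratics, so
# the least-squares projection is exact to machine precision).
toy_quadratic_fit <- function(center = 20, scale = 100, range = c(0, 30),
                              vcov = NULL, grid_step = 0.1) {
  spec <- spline_spec("quadratic_bspline",
                      internal_knots = c(8, 16, 24) * diff(range) / 30 + range[1],
                      boundary_knots = range, intercept = TRUE)
  grid <- seq(range[1], range[2], by = grid_step)
  B <- eval_spline(grid, spec)
  target <- (grid - center)^2 / scale
  beta <- drop(qr.solve(B, target))
  if (is.null(vcov)) vcov <- matrix(0, length(beta), length(beta))
  reduced_fit(beta, vcov, spec, temps = grid, grid_step = grid_step)
}

# A small fitted replicate from the U-shape scenario, cached per session.
fitted_u_replicate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- scenario_spec("u", n_years = 3)
      d <- generate_dataset(sc, seed = 404)
      cache <<- list(data = d, fit = fit_mmt_model(d, ma_window = sc$ma_window),
                     scenario = sc)
    }
    cache
  }
})
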