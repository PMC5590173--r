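# Independent oracles, deliberately naive: written against the defining
# formulas, not against the package implementation.

# Cox-de Boor recursion, literal: basis function i of order k on the
# augmented knot vector. The rightmost nonempty interval is closed so the
# right boundary evaluates.
deboor_basis <- function(x, knots, ord) {
  right <- knots[length(knots)]
  Bfun <- function(i, k) {
    if (k == 1L) {
      lo <- knots[i]; hi <- knots[i + 1L]
      ind <- x >= lo & x < hi
      if (lo < hi && hi == right) ind <- ind | x == hi
      as.numeric(ind)
    } else {
      d1 <- knots[i + k - 1L] - knots[i]
      d2 <- knots[i + k] - knots[i + 1L]
      t1 <- if (d1 > 0) (x - knots[i]) / d1 * Bfun(i, k - 1L) else 0
      t2 <- if (d2 > 0) (knots[i + k] - x) / d2 * Bfun(i + 1L, k - 1L) else 0
      t1 + t2
    }
  }
  vapply(seq_len(length(knots) - ord), Bfun, numeric(length(x)), k = ord)
}

# Literal tensor-product double sum over (j, k) with the inner lag sum:
# column (j, k) of row t is sum_l phi_j(x_{t-l}) psi_k(l).
crossbasis_oracle <- function(temps, tspec, C, L) {
  vx <- basis_dim(tspec)
  vl <- ncol(C)
  n <- length(temps)
  phi_all <- eval_spline(temps, tspec)
  out <- matrix(0, n - L, vx * vl)
  for (t in (L + 1L):n) {
    for (j in seq_len(vx)) {
      for (k in seq_len(vl)) {
        s <- 0
        for (l in 0:L) s <- s + phi_all[t - l, j] * C[l + 1L, k]
        out[t - L, (k - 1L) * vx + j] <- s
      }
    }
  }
  out
}

# Lag-cumulated curve at a constant temperature by direct summation of the
# cross-basis predictor over lags.
cum_curve_oracle <- function(x, eta, tspec, C, L) {
  vx <- basis_dim(tspec)
  vl <- ncol(C)
  phi <- eval_spline(x, tspec)
  s <- 0
  for (l in 0:L) {
    for (j in seq_len(vx)) {
      for (k in seq_len(vl)) {
        s <- s + phi[1L, j] * C[l + 1L, k] * eta[(k - 1L) * vx + j]
      }
    }
  }
  unname(s)
}

# Plain Poisson IRLS, coded from the scoring equations.
irls_poisson <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- numeric(ncol(X))
  beta[1L] <- log(mean(y) + 0.5)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, mu)
    newb <- fit$coefficients
    if (max(abs(newb - beta)) < tol) return(newb)
    beta <- newb
  }
  beta
}

# Literal per-draw relative-risk loop: RR_i = exp((Q_x - Q_theta_i) beta_i).
rr_loop_oracle <- function(fit, theta, beta_draws, x) {
  Qx <- eval_spline(x, fit$temp_spline)
  out <- numeric(length(theta))
  for (i in seq_along(theta)) {
    Qt <- eval_spline(theta[i], fit$temp_spline)
    out[i] <- exp(sum((Qx - Qt) * beta_draws[, i]))
  }
  out
}
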