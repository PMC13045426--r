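# Nonlinear Poisson-Boltzmann equation around an infinite charged cylinder
# in a 1:1 electrolyte, in reduced potential y = e psi / kB T:
#
#   y'' + y'/r = kappa^2 sinh(y),   y(a) = y_a,   y -> 0 as r -> infinity
#
# Solved by damped Newton relaxation of the finite-difference system on a
# logarithmic radial grid from the surface r = a to r = a + far/kappa, where
# the far boundary is clamped to zero. The log substitution t = log(r) turns
# the operator into y_tt = kappa^2 r^2 sinh(y) on a uniform grid, which
# concentrates nodes near the surface where the potential varies fastest.

# Thomas algorithm for a tridiagonal system (sub, diag, sup)
.tridiag_solve <- function(sub, diag, sup, rhs) {
  n <- length(diag)
  for (i in seq(2, n)) {
    m <- sub[i - 1] / diag[i - 1]
    diag[i] <- diag[i] - m * sup[i - 1]
    rhs[i] <- rhs[i] - m * rhs[i - 1]
  }
  x <- numeric(n)
  x[n] <- rhs[n] / diag[n]
  for (i in seq(n - 1, 1)) x[i] <- (rhs[i] - sup[i] * x[i + 1]) / diag[i]
  x
}

# Returns the reduced surface slope -dy/dr at r = a (positive for y_a > 0).
# tol is relative on the residual of the discrete system.
.pb_cylinder_slope <- function(y_a, a, kappa, n = 4000, far = 50,
                               tol = 1e-8, max_iter = 100) {
  stopifnot(a > 0, kappa > 0, is.finite(y_a))
  s <- sign(y_a)
  y_a <- abs(y_a)
  if (y_a == 0) return(0)
  r_out <- a + far / kappa
  tg <- seq(log(a), log(r_out), length.out = n)
  dt <- tg[2] - tg[1]
  r <- exp(tg)
  w <- kappa^2 * r^2

  # linearized (Debye-Hueckel) solution as the starting iterate;
  # scaled Bessel functions avoid underflow at large kappa * r
  k0 <- function(z) besselK(z, 0, expon.scaled = TRUE) * exp(-(z - kappa * a))
  y <- y_a * k0(kappa * r) / k0(kappa * a)
  y[1] <- y_a
  y[n] <- 0

  inner <- seq(2, n - 1)
  residual <- function(y) {
    (y[inner + 1] - 2 * y[inner] + y[inner - 1]) / dt^2 -
      w[inner] * sinh(y[inner])
  }
  scale <- max(w) * max(y_a, 1)

  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Fv <- residual(y)
    if (max(abs(Fv)) < tol * scale) { converged <- TRUE; break }
    dmain <- -2 / dt^2 - w[inner] * cosh(y[inner])
    off <- rep(1 / dt^2, n - 3)
    dy <- .tridiag_solve(off, dmain, off, -Fv)
    f0 <- sum(Fv^2)
    alpha <- 1
    repeat {
      y_try <- y
      y_try[inner] <- y[inner] + alpha * dy
      if (sum(residual(y_try)^2) < f0 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    step <- alpha * max(abs(dy))
    y <- y_try
    if (step < 1e-15) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf(paste0(
      "Poisson-Boltzmann relaxation did not converge: y_a = %.3g, ",
      "kappa*a = %.3g, residual = %.3g after %d iterations"),
      y_a, kappa * a, max(abs(residual(y))), max_iter))
  }
  # second-order one-sided derivative on the log grid, then chain rule
  dydt <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * dt)
  s * (-dydt / a)
}
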