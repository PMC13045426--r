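# Independent numerical oracles used across the suite. These deliberately
# avoid the code paths they check: Bessel functions come from their
# integral representations via adaptive quadrature, and the van der Waals
# oracles integrate the pairwise 1/r^6 Hamaker kernel over the two bodies.

# physical constants, restated independently of the package internals
orc <- list(
  e    = 1.602176634e-19,
  kB   = 1.380649e-23,
  eps0 = 8.8541878128e-12,
  NA_  = 6.02214076e23
)

# modified Bessel functions from their integral representations
k0_oracle <- function(z) {
  stats::integrate(function(t) exp(-z * cosh(t)), 0, 40,
                   rel.tol = 1e-12)$value
}
k1_oracle <- function(z) {
  stats::integrate(function(t) exp(-z * cosh(t)) * cosh(t), 0, 40,
                   rel.tol = 1e-12)$value
}

# Full nonretarded Hamaker integration between two perpendicular cylinders
# of radius R at center-to-center distance x0 (axes crossed at 90 deg).
# The integrals along both cylinder axes are analytic
# (int int du dv (u^2+v^2+c^2)^-3 = pi / (2 c^4)), leaving a 2-D
# quadrature over the two cross-section chords.
vdw_crossed_oracle <- function(x0, R, A_H, n = 3000) {
  z <- seq(-R + R / n, R - R / n, length.out = n)
  dz <- z[2] - z[1]
  w <- 2 * sqrt(pmax(R^2 - z^2, 0))
  M <- outer(z, z, function(z1, z2) 1 / (x0 + z2 - z1)^4)
  -(A_H / pi^2) * (pi / 2) * sum((w %o% w) * M) * dz^2
}

# Full nonretarded Hamaker integration between two parallel cylinders,
# per pair over length L. Integrating along the axes gives the kernel
# (3 pi / 8) rho^-5 between cross-section area elements; the double disk
# integral collapses to a 2-D integral against the disk-disk overlap
# (cross-correlation) function C(v).
vdw_parallel_oracle <- function(x0, R, A_H, L, nv = 4000, nphi = 720) {
  overlap <- function(v) {
    out <- numeric(length(v))
    inside <- v < 2 * R
    vi <- v[inside]
    out[inside] <- 2 * R^2 * acos(vi / (2 * R)) -
      (vi / 2) * sqrt(4 * R^2 - vi^2)
    out
  }
  v <- seq(0, 2 * R, length.out = nv + 1)[-1] - R / nv
  dv <- v[2] - v[1]
  phi <- seq(0, 2 * pi, length.out = nphi + 1)[-1]
  dphi <- phi[2] - phi[1]
  inner <- vapply(v, function(vv) {
    sum((x0^2 + vv^2 + 2 * x0 * vv * cos(phi))^(-2.5)) * dphi
  }, numeric(1))
  -(3 * A_H / (8 * pi)) * L * sum(v * overlap(v) * inner) * dv
}

# canonical worked-example inputs: short rigid lysozyme fibrils at pH 2.0
lys_geom <- function() fibril_geometry(D = 20.9 / 5.4, aspect_ratio = 95)
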