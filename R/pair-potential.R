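#' Cylinder-corrected effective line charge
#'
#' Reduces the finite-thickness cylinder to an equivalent line charge:
#' `lambda_eff = lambda exp(-kappa D/2) / ((kappa D/2) K1(kappa D/2))`.
#' By construction the identity
#' `A' = 2 pi lambda_eff^2 Q / kappa` holds exactly with the amplitude of
#' [electrostatic_amplitude()], and `lambda_eff -> lambda` as
#' `kappa D -> 0`.
#'
#' @param lambda Linear charge density in e/nm.
#' @param kappa Inverse Debye length in 1/nm.
#' @param D Bare diameter in nm.
#' @return Effective line charge in e/nm.
#' @export
effective_line_charge <- function(lambda, kappa, D) {
  if (any(kappa <= 0) || any(D <= 0)) abort("kappa and D must be positive")
  z <- kappa * D / 2
  lambda * exp(-z) / (z * besselK(z, 1))
}

#' Screened electrostatic pair potential of two rods
#'
#' Debye-Hueckel interaction of two line charges with cylinder-corrected
#' effective charge, in kT:
#' parallel rods (`theta = 0`), per pair over the full length `L`:
#' `U_par = 2 L lambda_eff^2 Q K0(kappa x)`;
#' crossed rods (`theta > 0`):
#' `U(theta) = (2 pi lambda_eff^2 Q / kappa) exp(-kappa x) / sin(theta)`,
#' which at `theta = 90` ties back to the amplitude identity as
#' `A' exp(-kappa x)`. Both branches are positive and strictly decreasing
#' in the center-to-center distance `x`.
#'
#' @param x Center-to-center distance in nm.
#' @param theta Relative orientation angle in degrees; 0 selects the
#'   parallel branch, (0, 90] the crossed branch.
#' @param L Rod length in nm (parallel branch only).
#' @param D Bare diameter in nm.
#' @param lambda Linear charge density in e/nm.
#' @param cond A [solution_conditions()].
#' @return Energy in kT.
#' @export
electrostatic_pair <- function(x, theta, L, D, lambda, cond) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (any(x <= 0)) abort("x must be > 0")
  if (theta < 0 || theta > 90) abort("theta must lie in [0, 90] degrees")
  lam_eff <- effective_line_charge(lambda, cond$kappa, D)
  if (theta == 0) {
    2 * L * lam_eff^2 * cond$Q * besselK(cond$kappa * x, 0)
  } else {
    (2 * pi * lam_eff^2 * cond$Q / cond$kappa) * exp(-cond$kappa * x) /
      sin(theta * pi / 180)
  }
}

#' Nonretarded van der Waals pair potential of two cylinders
#'
#' Near-contact (Derjaguin) closed forms in kT, with surface separation
#' `s = x - D`: parallel,
#' `U = -(A_H L / (12 sqrt(2) s^(3/2))) sqrt(R/2)` with `R = D/2`;
#' crossed (any `theta > 0`, evaluated at 90 degrees),
#' `U = -A_H R / (6 s)`. Both are attractive and vanish at large
#' separation. These are the leading `s -> 0` asymptotes of the full
#' pairwise Hamaker integration and overestimate the attraction when `s`
#' is comparable to `R`.
#'
#' @param x Center-to-center distance in nm (must exceed `D`).
#' @param theta Orientation angle in degrees; 0 = parallel.
#' @param D Bare diameter in nm.
#' @param L Rod length in nm (parallel branch only).
#' @param A_H Hamaker constant in kT.
#' @return Energy in kT (non-positive).
#' @export
vdw_pair <- function(x, theta, D, L, A_H = 3) {
  if (A_H < 0) abort("A_H must be >= 0")
  s <- x - D
  if (any(s <= 0)) abort("surface separation s = x - D must be > 0 (rods overlap)")
  R <- D / 2
  if (theta == 0) {
    -(A_H * L / (12 * sqrt(2) * s^1.5)) * sqrt(R / 2)
  } else {
    -A_H * R / (6 * s)
  }
}

#' Total rod-rod pair potential
#'
#' Sum of the screened electrostatic and van der Waals contributions.
#'
#' @inheritParams electrostatic_pair
#' @param geom A [fibril_geometry()].
#' @param A_H Hamaker constant in kT.
#' @return Energy in kT.
#' @export
total_pair_potential <- function(x, theta, geom, lambda, cond, A_H = 3) {
  stopifnot(inherits(geom, "fibril_geometry"))
  electrostatic_pair(x, theta, geom$L, geom$D, lambda, cond) +
    vdw_pair(x, theta, geom$D, geom$L, A_H)
}

#' Relative probability of crossed versus parallel rod orientation
#'
#' `P = exp(-(U_par - U_perp))` in kT units: the Boltzmann weight of the
#' parallel configuration relative to the perpendicular one at the same
#' center-to-center distance. `P = 1` when the energies are equal and may
#' exceed 1 when the parallel configuration is the lower-energy one.
#'
#' @param U_par,U_perp Energies in kT.
#' @return Dimensionless probability ratio, `> 0`.
#' @examples
#' relative_probability(log(100), 0) # 0.01
#' @export
relative_probability <- function(U_par, U_perp) {
  if (any(!is.finite(U_par)) || any(!is.finite(U_perp))) {
    abort("energies must be finite")
  }
  exp(-(U_par - U_perp))
}

#' Pair-potential curve over a distance grid
#'
#' Evaluates both orientation branches of the electrostatic, van der Waals
#' and total pair potentials on a grid of reduced center-to-center
#' distances, together with the relative orientation probability.
#'
#' @param geom A [fibril_geometry()].
#' @param lambda Linear charge density in e/nm.
#' @param cond A [solution_conditions()].
#' @param A_H Hamaker constant in kT.
#' @param x_over_D Grid of reduced distances (`> 1`).
#' @return A tibble with class `"fp_pair_curve"`: `x_over_D`, `x_nm`,
#'   `U_el_par`, `U_el_perp`, `U_vdW_par`, `U_vdW_perp`, `U_tot_par`,
#'   `U_tot_perp`, `P` (all energies in kT).
#' @examples
#' curve <- pair_potential_curve(reference_geometry("lysozyme"), 3.0,
#'                               solution_conditions(2, I_in = 0.02))
#' head(curve)
#' @export
pair_potential_curve <- function(geom, lambda, cond, A_H = 3,
                                 x_over_D = seq(1.05, 15, by = 0.05)) {
  stopifnot(inherits(geom, "fibril_geometry"))
  if (any(x_over_D <= 1)) abort("x_over_D must exceed 1 (no overlap)")
  x <- x_over_D * geom$D
  el_par <- electrostatic_pair(x, 0, geom$L, geom$D, lambda, cond)
  el_perp <- electrostatic_pair(x, 90, geom$L, geom$D, lambda, cond)
  vd_par <- vdw_pair(x, 0, geom$D, geom$L, A_H)
  vd_perp <- vdw_pair(x, 90, geom$D, geom$L, A_H)
  out <- tibble(
    x_over_D = x_over_D, x_nm = x,
    U_el_par = el_par, U_el_perp = el_perp,
    U_vdW_par = vd_par, U_vdW_perp = vd_perp,
    U_tot_par = el_par + vd_par, U_tot_perp = el_perp + vd_perp,
    P = relative_probability(el_par + vd_par, el_perp + vd_perp))
  class(out) <- c("fp_pair_curve", class(out))
  out
}

#' Solve for the nematic inter-fibril spacing
#'
#' Finds the reduced center-to-center distance at which the relative
#' orientation probability equals a benchmark value (0.012 by default, the
#' value calibrated at the measured nematic spacing of the reference
#' system). The outermost crossing of the benchmark on the bracket is
#' returned; strict monotonicity of `P(x)` across the crossing segment is
#' asserted at run time, and the root is located by bisection to 1e-4 in
#' `x/D`.
#'
#' @param P_target Benchmark relative probability.
#' @param geom A [fibril_geometry()].
#' @param lambda Linear charge density in e/nm.
#' @param cond A [solution_conditions()].
#' @param A_H Hamaker constant in kT.
#' @param bracket Search interval in `x/D`.
#' @return Reduced spacing `x/D` (dimensionless).
#' @export
solve_nematic_spacing <- function(P_target, geom, lambda, cond, A_H = 3,
                                  bracket = c(1.05, 50)) {
  stopifnot(inherits(geom, "fibril_geometry"))
  if (P_target <= 0) abort("P_target must be > 0")
  P_at <- function(xd) {
    relative_probability(
      total_pair_potential(xd * geom$D, 0, geom, lambda, cond, A_H),
      total_pair_potential(xd * geom$D, 90, geom, lambda, cond, A_H))
  }
  # P(x) need not be globally monotone: it falls steeply from its
  # near-contact value, passes a deep minimum where the parallel
  # electrostatic repulsion dominates, and relaxes to 1 from one side at
  # large x. The spacing of interest is the outermost crossing of the
  # benchmark, beyond which the orientation preference has decayed; the
  # crossing segment itself must be strictly monotone, which is asserted.
  grid <- seq(bracket[1], bracket[2], length.out = 1000)
  Pg <- vapply(grid, P_at, numeric(1))
  s <- sign(Pg - P_target)
  crossings <- which(diff(s) != 0)
  if (length(crossings) == 0) {
    abort(sprintf(
      "no solution: P ranges over [%.3g, %.3g] on the bracket, target %.3g",
      min(Pg), max(Pg), P_target))
  }
  i <- crossings[length(crossings)]
  seg <- seq(max(i - 1, 1), min(i + 2, length(grid)))
  dseg <- diff(Pg[seg])
  if (!(all(dseg > 0) || all(dseg < 0))) {
    abort("P(x) is not strictly monotone across the crossing segment; refine the bracket")
  }
  uniroot(function(xd) P_at(xd) - P_target,
          c(grid[i], grid[i + 1]), tol = 1e-4)$root
}
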