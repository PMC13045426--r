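#' Generalized Henry factor for a cylinder transverse to the field
#'
#' Retardation factor relating the transverse electrophoretic mobility of a
#' long cylinder to its surface potential,
#' `mu_perp = eps eps0 psi0 f(kappa a) / eta`. Uses Ohshima's closed-form
#' approximation, which interpolates smoothly between the thin-double-layer
#' (Smoluchowski, `f -> 1`) and thick-double-layer (Hueckel-type,
#' `f -> 1/2`) limits and is monotone non-decreasing in `kappa_a`.
#' The mobility parallel to the axis carries no retardation (`f = 1`).
#'
#' @param kappa_a Product of inverse Debye length and cylinder radius
#'   (dimensionless), `> 0`.
#' @return Dimensionless factor in (1/2, 1).
#' @examples
#' henry_factor_cylinder(c(0.01, 1, 100))
#' @export
henry_factor_cylinder <- function(kappa_a) {
  if (any(!is.finite(kappa_a)) || any(kappa_a <= 0)) {
    abort("kappa_a must be > 0")
  }
  0.5 * (1 + 1 / (1 + 2.55 / (kappa_a * (1 + exp(-kappa_a))))^2)
}

# orientation-averaged mobility factor: mu = eps eps0 psi0 (1 + 2 f)/(3 eta)
.orientation_factor <- function(kappa, D) {
  (1 + 2 * henry_factor_cylinder(kappa * D / 2)) / 3
}

#' Convert electrophoretic mobility to surface potential
#'
#' Inverts the orientation-averaged mobility of a freely rotating cylinder,
#' `mu = (mu_par + 2 mu_perp) / 3` with `mu_par = eps eps0 psi0 / eta` and
#' `mu_perp = eps eps0 psi0 f(kappa D/2) / eta`. The relation is linear in
#' `psi0`, so the inversion is algebraic; zero mobility maps to zero
#' potential.
#'
#' @param mobility Electrophoretic mobility in um cm / (V s)
#'   (1 um cm/(V s) = 1e-8 m^2/(V s)).
#' @param D Fibril diameter in nm.
#' @param cond A [solution_conditions()].
#' @param viscosity Solvent viscosity in Pa s.
#' @return Surface potential in mV (same sign as the mobility).
#' @examples
#' cond <- solution_conditions(2)
#' mobility_to_surface_potential(2.5, D = 3.9, cond = cond)
#' @export
mobility_to_surface_potential <- function(mobility, D, cond,
                                          viscosity = 0.933e-3) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (any(!is.finite(mobility))) abort("mobility must be finite")
  if (D <= 0) abort("D must be positive")
  mu_si <- mobility * 1e-8                       # m^2 / (V s)
  f <- .orientation_factor(cond$kappa, D)
  psi <- mu_si * viscosity / (.const$eps0 * cond$eps_r * f)   # V
  psi * 1e3
}

# forward model: surface potential (mV) -> mobility (um cm / (V s))
.surface_potential_to_mobility <- function(psi0_mV, D, cond,
                                           viscosity = 0.933e-3) {
  f <- .orientation_factor(cond$kappa, D)
  (.const$eps0 * cond$eps_r * psi0_mV * 1e-3 * f / viscosity) / 1e-8
}

#' Surface potential to linear charge density
#'
#' Solves the nonlinear Poisson-Boltzmann equation around a charged cylinder
#' of diameter `D` in a 1:1 electrolyte for the surface charge density that
#' sustains a given surface potential, and returns the linear charge density
#' `lambda = pi D sigma`. In the low-potential limit this reduces to the
#' Debye-Hueckel closed form
#' `lambda_DH = (pi D eps eps0 kappa psi0 / e) K1(kappa D/2) / K0(kappa D/2)`,
#' available via `method = "dh"`; the nonlinear solution exceeds it in
#' magnitude at high potentials (charge saturation asymmetry).
#'
#' @param psi0 Surface potential in mV.
#' @param D Fibril diameter in nm.
#' @param cond A [solution_conditions()].
#' @param method `"pb"` (nonlinear, default) or `"dh"` (linearized closed
#'   form).
#' @return A list with class `"charge_state"`: `psi0` (mV), `sigma`
#'   (e/nm^2), `lambda` (e/nm), `pH`. The identity `lambda = pi D sigma`
#'   holds exactly.
#' @examples
#' cond <- solution_conditions(2)
#' surface_potential_to_linear_charge(25, D = 3.9, cond = cond)
#' @export
surface_potential_to_linear_charge <- function(psi0, D, cond,
                                               method = c("pb", "dh")) {
  stopifnot(inherits(cond, "solution_conditions"))
  method <- match.arg(method)
  if (D <= 0) abort("D must be positive")
  kT <- .const$kB * cond$temperature
  a <- D / 2
  kappa <- cond$kappa
  if (psi0 == 0) {
    sigma <- 0
  } else if (method == "dh") {
    sigma_si <- .const$eps0 * cond$eps_r * (kappa * 1e9) * (psi0 * 1e-3) *
      besselK(kappa * a, 1) / besselK(kappa * a, 0)
    sigma <- sigma_si / .const$e / 1e18        # e / nm^2
  } else {
    y_a <- .const$e * psi0 * 1e-3 / kT
    slope <- .pb_cylinder_slope(y_a, a, kappa)  # -dy/dr at surface, 1/nm
    sigma_si <- .const$eps0 * cond$eps_r * (kT / .const$e) * slope * 1e9
    sigma <- sigma_si / .const$e / 1e18
  }
  structure(list(psi0 = psi0, sigma = sigma, lambda = pi * D * sigma,
                 pH = cond$pH),
            class = "charge_state")
}

# inverse of the above: linear charge density (e/nm) -> surface potential (mV)
.linear_charge_to_surface_potential <- function(lambda, D, cond,
                                                method = "pb") {
  if (lambda == 0) return(0)
  f <- function(psi) {
    surface_potential_to_linear_charge(psi, D, cond, method)$lambda -
      lambda
  }
  s <- sign(lambda)
  # lambda is strictly increasing in psi0; expand the bracket as needed
  hi <- 50
  while (s * f(s * hi) < 0 && hi < 6400) hi <- hi * 2
  uniroot(f, interval = sort(c(s * 1e-6, s * hi)), tol = 1e-10)$root
}

#' Linear charge density from mobility measurements
#'
#' Full electrokinetic chain for a table of mobility measurements: each row
#' is converted to a surface potential (generalized Henry inversion) and
#' then to a surface charge and linear charge density (nonlinear
#' Poisson-Boltzmann).
#'
#' @param data A data frame with columns `pH`, `I` (ionic strength, mol/L)
#'   and `mobility` (um cm / (V s)); an `sd` column, if present, is carried
#'   through.
#' @param D Fibril diameter in nm.
#' @param config An [fp_config()] supplying temperature, permittivity and
#'   viscosity.
#' @param method Passed to [surface_potential_to_linear_charge()].
#' @return A tibble: input columns plus `psi0_mV`, `sigma_e_nm2`,
#'   `lambda_e_nm`.
#' @examples
#' tbl <- tibble::tibble(pH = 2, I = 0.01, mobility = 2.8)
#' linear_charge_from_mobility(tbl, D = 3.9)
#' @export
linear_charge_from_mobility <- function(data, D, config = fp_config(),
                                        method = "pb") {
  req <- c("pH", "I", "mobility")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(data$I <= 0)) abort("ionic strength must be > 0")
  rows <- purrr::pmap(list(data$pH, data$I, data$mobility),
    function(pH, I, mob) {
      cond <- solution_conditions(pH, config$temperature, config$eps_r,
                                  I_nom = I)
      psi0 <- mobility_to_surface_potential(mob, D, cond,
                                            viscosity = config$viscosity)
      cs <- surface_potential_to_linear_charge(psi0, D, cond, method)
      tibble(psi0_mV = psi0, sigma_e_nm2 = cs$sigma, lambda_e_nm = cs$lambda)
    })
  dplyr::bind_cols(as_tibble(data), dplyr::bind_rows(rows))
}

#' Monotone-preserving interpolant of charge density versus pH
#'
#' Fits a monotonicity-preserving cubic interpolant (Fritsch-Carlsen) through
#' tabulated `(pH, lambda)` points, the smooth charge-versus-pH curve used to
#' drive the phase-diagram pipeline. The interpolant passes through the
#' input points exactly and introduces no spurious extrema between knots.
#'
#' @param data A data frame with columns `pH` and `lambda` (e/nm), at least
#'   three rows, `pH` strictly increasing.
#' @return A function `lambda(pH)`.
#' @examples
#' fn <- smooth_charge_vs_ph(
#'   tibble::tibble(pH = c(2, 4, 7), lambda = c(3, 2, 1.17)))
#' fn(3)
#' @export
smooth_charge_vs_ph <- function(data) {
  if (!all(c("pH", "lambda") %in% names(data))) {
    abort("data must have columns pH and lambda")
  }
  pH <- data$pH
  lambda <- data$lambda
  if (anyDuplicated(pH)) abort("duplicate pH values")
  if (length(pH) < 3) abort("at least three (pH, lambda) points are required")
  if (is.unsorted(pH, strictly = TRUE)) {
    abort("pH values must be strictly increasing")
  }
  splinefun(pH, lambda, method = "monoH.FC")
}
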