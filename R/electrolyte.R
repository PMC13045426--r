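#' Bjerrum length
#'
#' Distance at which two elementary charges in a dielectric medium interact
#' with thermal energy kT: `Q = e^2 / (4 pi eps0 eps_r kB T)`. In water at
#' 23 degC this evaluates to about 0.7 nm.
#'
#' @param temperature Temperature in K.
#' @param eps_r Relative permittivity of the medium.
#' @return Bjerrum length in nm.
#' @examples
#' bjerrum_length(296.15, 78.4) # ~0.72 nm
#' @export
bjerrum_length <- function(temperature = 296.15, eps_r = 78.4) {
  stopifnot(is.numeric(temperature), is.numeric(eps_r))
  if (any(temperature <= 0) || any(eps_r <= 0)) {
    abort("temperature and eps_r must be positive")
  }
  with(.const, e^2 / (4 * pi * eps0 * eps_r * kB * temperature)) * 1e9
}

#' Debye screening length
#'
#' `kappa^-1 = sqrt(eps0 eps_r kB T / (2 NA e^2 I * 1e3))` for a 1:1
#' electrolyte of ionic strength `I` in mol/L. Halves when `I` is quadrupled.
#'
#' @param I Ionic strength in mol/L.
#' @inheritParams bjerrum_length
#' @return Debye length in nm.
#' @examples
#' debye_length(0.1) # ~0.96 nm
#' @export
debye_length <- function(I, temperature = 296.15, eps_r = 78.4) {
  if (any(!is.finite(I)) || any(I <= 0)) abort("ionic strength must be > 0")
  if (any(temperature <= 0) || any(eps_r <= 0)) {
    abort("temperature and eps_r must be positive")
  }
  with(.const,
       sqrt(eps0 * eps_r * kB * temperature / (2 * NA_ * e^2 * I * 1e3))) * 1e9
}

#' Inverse Debye length
#'
#' @inheritParams debye_length
#' @return kappa in 1/nm.
#' @export
inverse_debye_length <- function(I, temperature = 296.15, eps_r = 78.4) {
  1 / debye_length(I, temperature, eps_r)
}

#' Nominal ionic strength of pH-adjusted water
#'
#' Ionic strength `I = 1/2 sum z_i^2 c_i` of pure water titrated to a target
#' pH with a strong monoprotic acid (HCl below neutrality) or strong base
#' (NaOH above), counting H+, OH- and the spectator counterion fixed by
#' electroneutrality. The water ion product is fixed at 1e-14.
#'
#' @param pH Target pH, strictly between 0 and 14.
#' @return Ionic strength in mol/L.
#' @examples
#' nominal_ionic_strength(2)  # 0.01
#' nominal_ionic_strength(7)  # 1e-7
#' @export
nominal_ionic_strength <- function(pH) {
  if (any(!is.finite(pH)) || any(pH <= 0) || any(pH >= 14)) {
    abort("pH must lie strictly between 0 and 14")
  }
  h  <- 10^(-pH)
  oh <- 1e-14 / h
  # electroneutrality: counterion concentration balances the excess of H+/OH-
  counter <- abs(h - oh)
  0.5 * (h + oh + counter)
}

#' Solution conditions
#'
#' Container for the electrolyte state of one sample: pH, temperature,
#' permittivity, the nominal ionic strength of the titrated solvent and,
#' when known (e.g. after Donnan inference), the internal ionic strength of
#' the fibril-rich phase. Derived Bjerrum length and inverse Debye length
#' are attached; `kappa` uses the internal ionic strength when set, else the
#' nominal one.
#'
#' @param pH Sample pH.
#' @param temperature Temperature in K.
#' @param eps_r Relative permittivity.
#' @param I_nom Nominal ionic strength in mol/L; defaults to
#'   [nominal_ionic_strength()] at `pH`.
#' @param I_in Internal (Donnan-adjusted) ionic strength in mol/L, or `NULL`
#'   when not yet solved. Must be `>= I_nom`: counterion retention can only
#'   add ions.
#' @return A list with class `"solution_conditions"`: `pH`, `temperature`,
#'   `eps_r`, `I_nom`, `I_in`, `Q` (nm), `kappa` (1/nm).
#' @examples
#' solution_conditions(2)
#' @export
solution_conditions <- function(pH, temperature = 296.15, eps_r = 78.4,
                                I_nom = NULL, I_in = NULL) {
  if (is.null(I_nom)) I_nom <- nominal_ionic_strength(pH)
  if (!is.finite(I_nom) || I_nom <= 0) abort("I_nom must be > 0")
  if (!is.null(I_in)) {
    if (!is.finite(I_in) || I_in < I_nom) {
      abort("I_in must be finite and >= I_nom (counterion retention only adds ions)")
    }
  }
  I_eff <- if (is.null(I_in)) I_nom else I_in
  structure(
    list(pH = pH, temperature = temperature, eps_r = eps_r,
         I_nom = I_nom, I_in = I_in,
         Q = bjerrum_length(temperature, eps_r),
         kappa = inverse_debye_length(I_eff, temperature, eps_r)),
    class = "solution_conditions")
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf("<solution_conditions> pH %.2f, T = %.2f K, eps_r = %.1f\n",
              x$pH, x$temperature, x$eps_r))
  cat(sprintf("  I_nom = %.4g M, I_in = %s M\n", x$I_nom,
              if (is.null(x$I_in)) "unset" else sprintf("%.4g", x$I_in)))
  cat(sprintf("  Q = %.3f nm, kappa^-1 = %.3f nm\n", x$Q, 1 / x$kappa))
  invisible(x)
}

# update conditions with a solved internal ionic strength
set_internal_ionic_strength <- function(cond, I_in) {
  solution_conditions(cond$pH, cond$temperature, cond$eps_r,
                      I_nom = cond$I_nom, I_in = I_in)
}
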