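# CODATA 2018 values, SI units
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  NA_  = 6.02214076e23      # Avogadro number, 1/mol
)

# Euler-Mascheroni constant, enters the effective-diameter bracket
.euler_gamma <- 0.5772156649015329

#' Analysis configuration
#'
#' Bundles the physical constants and model defaults shared across the
#' pipeline: solvent properties at the working temperature, fibril and water
#' densities for the volume-fraction to weight-percent conversion, the
#' Onsager base constant of the isotropic-nematic threshold, the Hamaker
#' constant of the van der Waals pair terms, and the linear-charge-density
#' threshold below which dense samples are classified as liquid-liquid
#' phase separated rather than liquid-crystalline.
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param temperature Temperature in K. Default 296.15 (23 degC).
#' @param eps_r Relative permittivity of the solvent. Default 78.4 (water at
#'   23 degC).
#' @param viscosity Solvent dynamic viscosity in Pa s. Default 0.933e-3
#'   (water at 23 degC).
#' @param rho_af Fibril mass density in g/mL. Default 1.3.
#' @param rho_w Solvent mass density in g/mL. Default 1.0.
#' @param b0 Base constant of the hard-rod isotropic binodal,
#'   `phi = b0 * D/L`. Default 3.290 (coexistence constant of the charged-rod
#'   second-virial theory); 3.340 (nematic branch) selectable.
#' @param hamaker_kT Hamaker constant in units of kT. Default 3.
#' @param lambda_llps Linear charge density (e/nm) at or below which dense
#'   samples demix as two isotropic liquids. Default 1.0.
#' @param ... Additional named values are an error.
#'
#' @return A named list with class `"fp_config"`.
#' @examples
#' cfg <- fp_config()
#' cfg$b0
#' @export
fp_config <- function(temperature = 296.15, eps_r = 78.4,
                      viscosity = 0.933e-3, rho_af = 1.3, rho_w = 1.0,
                      b0 = 3.290, hamaker_kT = 3, lambda_llps = 1.0, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(paste0("unknown configuration keys: ",
                 paste(names(extra), collapse = ", ")))
  }
  vals <- list(temperature = temperature, eps_r = eps_r,
               viscosity = viscosity, rho_af = rho_af, rho_w = rho_w,
               b0 = b0, hamaker_kT = hamaker_kT, lambda_llps = lambda_llps)
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("configuration values must be positive finite scalars: ",
                 paste(bad, collapse = ", ")))
  }
  structure(vals, class = "fp_config")
}

#' @export
print.fp_config <- function(x, ...) {
  cat("<fp_config>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}
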