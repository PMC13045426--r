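#' Electrostatic interaction amplitude of two charged rods
#'
#' Debye-Hueckel amplitude of the screened interaction between two charged
#' cylinders,
#' `A' = 8 pi lambda^2 Q exp(-kappa D) / (kappa^3 D^2 K1(kappa D / 2)^2)`,
#' which scales exactly as `lambda^2`.
#'
#' @param lambda Linear charge density in e/nm (`>= 0`).
#' @param Q Bjerrum length in nm.
#' @param kappa Inverse Debye length in 1/nm.
#' @param D Bare diameter in nm.
#' @return Dimensionless amplitude.
#' @examples
#' electrostatic_amplitude(3, 0.7, 0.3, 3.9)
#' @export
electrostatic_amplitude <- function(lambda, Q, kappa, D) {
  if (any(lambda < 0)) abort("lambda must be >= 0")
  if (any(Q <= 0) || any(kappa <= 0) || any(D <= 0)) {
    abort("Q, kappa and D must be positive")
  }
  8 * pi * lambda^2 * Q * exp(-kappa * D) /
    (kappa^3 * D^2 * besselK(kappa * D / 2, 1)^2)
}

#' Electrostatic effective diameter
#'
#' The excluded-volume diameter of a charged rod exceeds the bare diameter
#' by the screening-length-scaled logarithm of the interaction amplitude:
#' `D_eff = D + kappa^-1 (ln A' + C_E + ln 2 - 1/2)` with `C_E` Euler's
#' constant. When the bracket is negative (very weak charge) the result is
#' clamped at `D`: an effective diameter below the physical one has no
#' excluded-volume meaning.
#'
#' @param D Bare diameter in nm.
#' @param kappa Inverse Debye length in 1/nm.
#' @param A_prime Amplitude from [electrostatic_amplitude()].
#' @return Effective diameter in nm, `>= D`.
#' @examples
#' effective_diameter(3.9, 1 / 3.05, 50)
#' @export
effective_diameter <- function(D, kappa, A_prime) {
  if (any(D <= 0) || any(kappa <= 0)) abort("D and kappa must be positive")
  if (any(A_prime < 0)) abort("A_prime must be >= 0")
  if (any(A_prime == 0)) {
    warn("A_prime = 0 (neutral rod): effective diameter equals the bare diameter")
    A_prime <- pmax(A_prime, .Machine$double.xmin)
  }
  d_eff <- D + (1 / kappa) * (log(A_prime) + .euler_gamma + log(2) - 0.5)
  pmax(d_eff, D)
}

#' Twisting factor
#'
#' `h = 1 / (kappa D_eff)`: penalizes parallel alignment of charged rods in
#' the coexistence theory; decreases with increasing ionic strength.
#'
#' @param kappa Inverse Debye length in 1/nm.
#' @param D_eff Effective diameter in nm.
#' @return Dimensionless twisting factor.
#' @export
twisting_factor <- function(kappa, D_eff) {
  if (any(kappa <= 0) || any(D_eff <= 0)) {
    abort("kappa and D_eff must be positive")
  }
  1 / (kappa * D_eff)
}

#' Electrostatic rod parameters for one (geometry, conditions, charge) triple
#'
#' Evaluates the full electrostatic dressing of a charged rod: amplitude
#' `A'`, effective diameter, twisting factor and the composite threshold
#' prefactor `b0 / (1 - 0.75 h)`.
#'
#' @param geom A [fibril_geometry()].
#' @param lambda Linear charge density in e/nm.
#' @param cond A [solution_conditions()].
#' @param b0 Base constant of the hard-rod isotropic binodal.
#' @return A list with class `"electrostatic_rod_params"`: `A_prime`,
#'   `D_eff` (nm), `h`, `C_E`, `prefactor`, plus the `kappa` and `b0` used.
#' @export
electrostatic_rod_params <- function(geom, lambda, cond, b0 = 3.290) {
  stopifnot(inherits(geom, "fibril_geometry"),
            inherits(cond, "solution_conditions"))
  A_prime <- electrostatic_amplitude(lambda, cond$Q, cond$kappa, geom$D)
  D_eff <- if (A_prime == 0) geom$D else
    effective_diameter(geom$D, cond$kappa, A_prime)
  h <- twisting_factor(cond$kappa, D_eff)
  structure(list(A_prime = A_prime, D_eff = D_eff, h = h,
                 C_E = .euler_gamma, prefactor = b0 / (1 - 0.75 * h),
                 kappa = cond$kappa, b0 = b0),
            class = "electrostatic_rod_params")
}

#' Threshold volume fraction of the isotropic-nematic transition
#'
#' Charged-rod second-virial threshold
#' `phi_IN = b0 (1 - 0.75 h)^-1 D^2 / (L D_eff)`. In the neutral hard-rod
#' limit (`h = 0`, `D_eff = D`) this reduces to the Onsager value
#' `b0 D / L`. Increasing `D_eff` lowers the threshold; a larger twisting
#' factor raises it. The twist correction diverges at `h = 4/3`, outside
#' the regime of the theory.
#'
#' @param geom A [fibril_geometry()].
#' @param params An [electrostatic_rod_params()].
#' @return Threshold volume fraction (dimensionless).
#' @export
threshold_volume_fraction <- function(geom, params) {
  stopifnot(inherits(geom, "fibril_geometry"),
            inherits(params, "electrostatic_rod_params"))
  if (params$h >= 4 / 3) {
    abort(sprintf(
      "twisting factor h = %.3f >= 4/3: the twist correction diverges, outside the regime of the coexistence theory",
      params$h))
  }
  params$b0 / (1 - 0.75 * params$h) * geom$D^2 / (geom$L * params$D_eff)
}

#' Volume fraction to weight percent, and back
#'
#' `c (wt%) = 100 phi rho_AF / (phi rho_AF + (1 - phi) rho_w)`; the inverse
#' is its exact algebraic inversion, so the round trip is the identity.
#'
#' @param phi Volume fraction in \[0, 1\].
#' @param c_wt Weight concentration in wt% (for the inverse).
#' @param rho_af Fibril density in g/mL.
#' @param rho_w Solvent density in g/mL.
#' @return Weight percent (or volume fraction for the inverse).
#' @examples
#' wt_from_volume_fraction(0.01)
#' volume_fraction_from_wt(wt_from_volume_fraction(0.01))
#' @export
wt_from_volume_fraction <- function(phi, rho_af = 1.3, rho_w = 1.0) {
  if (any(phi < 0) || any(phi > 1)) abort("phi must lie in [0, 1]")
  100 * phi * rho_af / (phi * rho_af + (1 - phi) * rho_w)
}

#' @rdname wt_from_volume_fraction
#' @export
volume_fraction_from_wt <- function(c_wt, rho_af = 1.3, rho_w = 1.0) {
  if (any(c_wt < 0) || any(c_wt > 100)) abort("c_wt must lie in [0, 100]")
  f <- c_wt / 100
  f * rho_w / (rho_af - f * (rho_af - rho_w))
}

#' Predict the isotropic-nematic threshold concentration
#'
#' Deterministic composition of the full charged-rod chain:
#' kappa from the solution's ionic strength (internal if set, nominal
#' otherwise, with a warning), then `A'`, effective diameter, twisting
#' factor, threshold volume fraction, and conversion to wt%.
#'
#' @param geom A [fibril_geometry()].
#' @param lambda Linear charge density in e/nm.
#' @param cond A [solution_conditions()].
#' @param config An [fp_config()] supplying `b0` and the densities.
#' @param quiet Suppress the nominal-ionic-strength fallback warning.
#' @return A one-row tibble: `pH`, `lambda_e_nm`, `I_M`, `kappa_nm1`,
#'   `A_prime`, `D_eff_nm`, `h`, `prefactor`, `twist_correction`
#'   (`(1 - 0.75 h)^-1` alone), `phi_IN`, `c_IN_wt`.
#' @examples
#' geom <- reference_geometry("lysozyme")
#' cond <- solution_conditions(2, I_in = 0.02)
#' predict_threshold_concentration(geom, 3.0, cond)
#' @export
predict_threshold_concentration <- function(geom, lambda, cond,
                                            config = fp_config(),
                                            quiet = FALSE) {
  stopifnot(inherits(geom, "fibril_geometry"),
            inherits(cond, "solution_conditions"))
  if (is.null(cond$I_in) && !quiet) {
    warn("I_in unset: falling back to the nominal ionic strength")
  }
  I_used <- if (is.null(cond$I_in)) cond$I_nom else cond$I_in
  params <- electrostatic_rod_params(geom, lambda, cond, b0 = config$b0)
  phi <- threshold_volume_fraction(geom, params)
  tibble(
    pH = cond$pH, lambda_e_nm = lambda, I_M = I_used,
    kappa_nm1 = cond$kappa, A_prime = params$A_prime,
    D_eff_nm = params$D_eff, h = params$h,
    prefactor = params$prefactor,
    twist_correction = 1 / (1 - 0.75 * params$h),
    phi_IN = phi,
    c_IN_wt = wt_from_volume_fraction(phi, config$rho_af, config$rho_w))
}

#' Infer the internal ionic strength from an observed transition
#'
#' Fibrils dialyzed against pH-adjusted water retain counterions by Donnan
#' partitioning, so the ionic strength inside the fibril-rich phase exceeds
#' the nominal one. This solver adjusts the internal ionic strength by
#' bisection on `[I_nom, I_max]` until the predicted isotropic-nematic
#' threshold matches the observed start concentration, to a relative
#' tolerance of 1e-6. The predicted threshold is strictly increasing in
#' ionic strength (stronger screening shrinks the effective diameter);
#' monotonicity over the bracket is asserted at run time.
#'
#' @param c_obs Observed mean start concentration of the liquid-crystalline
#'   coexistence, wt%.
#' @param geom A [fibril_geometry()].
#' @param lambda Linear charge density in e/nm.
#' @param cond A [solution_conditions()]; its `I_nom` is the lower bracket.
#' @param config An [fp_config()].
#' @param I_max Upper bracket in mol/L (default 1, far above any plausible
#'   Donnan enhancement).
#' @param tol Relative tolerance on the matched concentration.
#' @return A list: `I_in` (mol/L), `prediction` (the one-row tibble from
#'   [predict_threshold_concentration()] at the solution), `c_obs`.
#' @examples
#' geom <- reference_geometry("lysozyme")
#' cond <- solution_conditions(2)
#' sol <- solve_internal_ionic_strength(1.49, geom, 3.0, cond)
#' sol$prediction$prefactor
#' @export
solve_internal_ionic_strength <- function(c_obs, geom, lambda, cond,
                                          config = fp_config(), I_max = 1,
                                          tol = 1e-6) {
  stopifnot(inherits(geom, "fibril_geometry"),
            inherits(cond, "solution_conditions"))
  if (!is.finite(c_obs) || c_obs <= 0) abort("c_obs must be > 0")
  c_at <- function(I) {
    cnd <- set_internal_ionic_strength(cond, I)
    predict_threshold_concentration(geom, lambda, cnd, config)$c_IN_wt
  }
  grid <- exp(seq(log(cond$I_nom), log(I_max), length.out = 40))
  grid[1] <- cond$I_nom
  cg <- vapply(grid, c_at, numeric(1))
  # restrict to the strictly increasing part of the bracket (the chain can
  # turn over when screening starts to erode the twist correction faster
  # than the effective diameter)
  turn <- which(diff(cg) <= 0)
  if (length(turn) > 0) {
    keep <- seq_len(turn[1])
    if (length(keep) < 3) {
      abort("predicted threshold concentration is not strictly increasing in I_in over the bracket")
    }
    grid <- grid[keep]
    cg <- cg[keep]
  }
  c_lo <- cg[1]
  c_hi <- cg[length(cg)]
  if (c_obs < c_lo || c_obs > c_hi) {
    abort(sprintf(
      "no solution: c_obs = %.3g wt%% outside the achievable interval [%.3g, %.3g] wt%% for I_in in [%.3g, %.3g] M",
      c_obs, c_lo, c_hi, grid[1], grid[length(grid)]))
  }
  root <- uniroot(function(I) c_at(I) - c_obs,
                  interval = range(grid),
                  tol = .Machine$double.eps^0.75)$root
  # refine to the stated relative tolerance on concentration
  stopifnot(abs(c_at(root) - c_obs) / c_obs < tol)
  cnd <- set_internal_ionic_strength(cond, root)
  list(I_in = root,
       prediction = predict_threshold_concentration(geom, lambda, cnd, config),
       c_obs = c_obs)
}

#' Classify the phase regime of one state point
#'
#' Liquid-liquid phase separation (two isotropic liquids) takes over from
#' liquid-crystalline demixing when the fibril charge falls to about
#' 1 e/nm; above that charge, dense samples demix into isotropic plus
#' nematic. Vectorized over all arguments.
#'
#' @param lambda Linear charge density in e/nm.
#' @param c Sample concentration in wt%.
#' @param c_IN Predicted isotropic-nematic threshold in wt%.
#' @param lambda_llps Charge threshold for the liquid-liquid regime (e/nm).
#' @param c_onset Concentration onset of liquid-liquid demixing in wt%;
#'   defaults to `c_IN`.
#' @return Character vector: `"isotropic"`, `"LLCPS"` or `"LLPS"`.
#' @examples
#' classify_regime(3, c(1, 2), c_IN = 1.49)
#' classify_regime(0.9, 1, c_IN = 1.49, c_onset = 0.5)
#' @export
classify_regime <- function(lambda, c, c_IN, lambda_llps = 1.0,
                            c_onset = NULL) {
  if (is.null(c_onset)) c_onset <- c_IN
  out <- rep("isotropic", length.out = max(length(lambda), length(c)))
  # tolerant comparison: a sample sitting numerically on the threshold
  # (e.g. the matched observation itself) counts as demixed
  eps <- 1e-9
  llps <- lambda <= lambda_llps & c >= c_onset * (1 - eps)
  llcps <- !llps & c >= c_IN * (1 - eps)
  out[llcps] <- "LLCPS"
  out[llps] <- "LLPS"
  out
}

#' Assemble a phase diagram from observed transitions
#'
#' Runs the full per-pH chain over a table of observed liquid-crystalline
#' start concentrations: charge density from the supplied `lambda(pH)`
#' curve, internal ionic strength solved from the observed mean start
#' concentration, the predicted threshold and its electrostatic dressing,
#' and the regime label. Rows whose solve fails are flagged in the `status`
#' column rather than aborting the assembly.
#'
#' @param observations A data frame sorted by `pH`, with columns `pH` and
#'   `c_mean` (mean observed start concentration, wt%); optional `c_min`.
#' @param lambda_of_ph A function `lambda(pH)` (e.g. from
#'   [smooth_charge_vs_ph()]) or a data frame with columns `pH`, `lambda`.
#' @param geom A [fibril_geometry()].
#' @param config An [fp_config()].
#' @return A tibble, one row per observation: the observation columns plus
#'   `lambda_e_nm`, `I_nom_M`, `I_in_M`, `kappa_nm1`, `A_prime`, `D_eff_nm`,
#'   `h`, `prefactor`, `twist_correction`, `phi_IN`, `c_IN_wt`, `regime`,
#'   `status`.
#' @examples
#' obs <- tibble::tibble(pH = c(2, 4), c_mean = c(1.49, 0.90))
#' lam <- smooth_charge_vs_ph(
#'   tibble::tibble(pH = c(2, 4, 7), lambda = c(3, 2, 1.17)))
#' build_phase_diagram(obs, lam, reference_geometry("lysozyme"))
#' @export
build_phase_diagram <- function(observations, lambda_of_ph, geom,
                                config = fp_config()) {
  if (!all(c("pH", "c_mean") %in% names(observations))) {
    abort("observations must have columns pH and c_mean")
  }
  if (is.unsorted(observations$pH)) {
    abort("observations must be sorted by pH")
  }
  lam_fn <- if (is.function(lambda_of_ph)) lambda_of_ph else
    smooth_charge_vs_ph(lambda_of_ph)
  rows <- purrr::pmap(list(observations$pH, observations$c_mean),
    function(pH, c_mean) {
      lambda <- lam_fn(pH)
      cond <- solution_conditions(pH, config$temperature, config$eps_r)
      res <- tryCatch(
        solve_internal_ionic_strength(c_mean, geom, lambda, cond, config),
        error = function(e) e)
      if (inherits(res, "error")) {
        return(tibble(lambda_e_nm = lambda, I_nom_M = cond$I_nom,
                      I_in_M = NA_real_, kappa_nm1 = NA_real_,
                      A_prime = NA_real_, D_eff_nm = NA_real_, h = NA_real_,
                      prefactor = NA_real_, twist_correction = NA_real_,
                      phi_IN = NA_real_, c_IN_wt = NA_real_,
                      regime = NA_character_,
                      status = conditionMessage(res)))
      }
      p <- res$prediction
      tibble(lambda_e_nm = lambda, I_nom_M = cond$I_nom, I_in_M = res$I_in,
             kappa_nm1 = p$kappa_nm1, A_prime = p$A_prime,
             D_eff_nm = p$D_eff_nm, h = p$h, prefactor = p$prefactor,
             twist_correction = p$twist_correction, phi_IN = p$phi_IN,
             c_IN_wt = p$c_IN_wt,
             regime = classify_regime(lambda, c_mean, p$c_IN_wt,
                                      config$lambda_llps),
             status = "ok")
    })
  out <- dplyr::bind_cols(as_tibble(observations), dplyr::bind_rows(rows))
  class(out) <- c("fp_phase_diagram", class(out))
  out
}
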