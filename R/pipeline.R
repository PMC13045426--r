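#' End-to-end analysis wrappers
#'
#' File-in, tibble-out orchestration of the module chains, mirroring how
#' the analyses combine in practice. Each wrapper validates its input,
#' runs the corresponding module functions with the shared configuration,
#' and optionally writes its result table; all are deterministic given
#' inputs and configuration.
#'
#' * `analyze_charge()`: mobility table to linear charge density per pH.
#' * `analyze_phase_diagram()`: observed transitions plus a charge table
#'   to the full per-pH diagram (solved internal ionic strength,
#'   predicted threshold, prefactor, regime).
#' * `analyze_pair_potential()`: potential curves and the nematic spacing
#'   at one pH, given a solved diagram row.
#' * `analyze_saxs()`: form-factor fit of a dilute profile and, when a
#'   dense profile is supplied, the structure factor, its peak and the
#'   real-space periodicity.
#' * `analyze_frap()`: trace normalization, recovery fit and derived
#'   metrics.
#' * `analyze_morphometry()`: per-fibril contour statistics and the
#'   worm-like-chain persistence length.
#'
#' @param mobility Path to a mobility CSV (see [read_mobility_table()]) or
#'   an equivalent data frame.
#' @param observations Path to a phase-observation CSV (see
#'   [read_phase_observations()]) or an equivalent data frame.
#' @param charge_table Data frame with columns `pH`, `lambda` (e.g. the
#'   output of `analyze_charge()`, renamed), or a `lambda(pH)` function.
#' @param diagram_row One row of an `analyze_phase_diagram()` result.
#' @param dilute,dense SAXS profile paths or data frames (`q`, `I`).
#' @param trace FRAP trace path or data frame.
#' @param contours Contour-trace path or data frame.
#' @param geom A [fibril_geometry()].
#' @param D Fibril diameter in nm.
#' @param config An [fp_config()].
#' @param bleach_index,omega See [fit_frap_recovery()].
#' @param N_ratio Number-density ratio dense/dilute for the structure
#'   factor.
#' @param P_target Relative-probability benchmark for the nematic
#'   spacing.
#' @param out Optional path; when given, the main result table is written
#'   there as CSV.
#' @return See the individual descriptions; all results are tibbles or
#'   fitted objects from the owning modules.
#' @name fp_pipeline
NULL

.as_table <- function(x, reader) if (is.character(x)) reader(x) else as_tibble(x)

#' @rdname fp_pipeline
#' @export
analyze_charge <- function(mobility, D, config = fp_config(), out = NULL) {
  tbl <- .as_table(mobility, read_mobility_table)
  res <- linear_charge_from_mobility(tbl, D, config)
  if (!is.null(out)) write_result_csv(res, out)
  res
}

#' @rdname fp_pipeline
#' @export
analyze_phase_diagram <- function(observations, charge_table, geom,
                                  config = fp_config(), out = NULL) {
  obs <- .as_table(observations, read_phase_observations)
  res <- build_phase_diagram(obs, charge_table, geom, config)
  if (!is.null(out)) write_result_csv(res, out)
  res
}

#' @rdname fp_pipeline
#' @export
analyze_pair_potential <- function(diagram_row, geom, config = fp_config(),
                                   P_target = 0.012, out = NULL) {
  if (nrow(diagram_row) != 1 || is.na(diagram_row$I_in_M)) {
    abort("diagram_row must be a single successfully solved diagram row")
  }
  cond <- solution_conditions(diagram_row$pH, config$temperature,
                              config$eps_r, I_in = diagram_row$I_in_M)
  curve <- pair_potential_curve(geom, diagram_row$lambda_e_nm, cond,
                                A_H = config$hamaker_kT)
  spacing <- tryCatch(
    solve_nematic_spacing(P_target, geom, diagram_row$lambda_e_nm, cond,
                          A_H = config$hamaker_kT),
    error = function(e) NA_real_)
  attr(curve, "x_nematic_over_D") <- spacing
  if (!is.null(out)) write_result_csv(curve, out)
  curve
}

#' @rdname fp_pipeline
#' @export
analyze_saxs <- function(dilute, dense = NULL, N_ratio = NULL,
                         config = fp_config(), out = NULL) {
  ref <- .as_table(dilute, read_saxs_profile)
  fit <- fit_form_factor(ref)
  res <- list(form_factor_fit = fit)
  if (!is.null(dense)) {
    if (is.null(N_ratio)) abort("N_ratio is required with a dense profile")
    dn <- .as_table(dense, read_saxs_profile)
    sf <- structure_factor(dn, ref, N_ratio)
    res$structure_factor <- sf
    res$q_star <- tryCatch(find_sf_peak(sf), error = function(e) NA_real_)
    res$d_nm <- if (is.na(res$q_star)) NA_real_ else
      spacing_from_peak(res$q_star)
    if (!is.null(out)) write_result_csv(sf, out)
  }
  res
}

#' @rdname fp_pipeline
#' @export
analyze_frap <- function(trace, bleach_index = NULL, omega = NA_real_,
                         config = fp_config()) {
  tr <- .as_table(trace, read_frap_trace)
  if (is.null(bleach_index)) bleach_index <- attr(tr, "bleach_index")
  if (is.null(bleach_index)) abort("bleach_index is required")
  if (is.na(omega) && !is.null(attr(tr, "omega"))) omega <- attr(tr, "omega")
  fit_frap_recovery(normalize_frap(tr, bleach_index), bleach_index, omega)
}

#' @rdname fp_pipeline
#' @export
analyze_morphometry <- function(contours, config = fp_config(),
                                out = NULL) {
  tr <- .as_table(contours, read_contour_traces)
  fit <- fit_persistence_length(tr)
  if (!is.null(out)) write_result_csv(fit$per_fibril, out)
  fit
}
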