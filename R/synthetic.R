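# evaluate code under a fixed RNG seed, restoring global RNG state after
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate 2-D worm-like-chain fibril contours
#'
#' Discretized chains equilibrated in two dimensions: successive segment
#' turning angles are independent Gaussians of variance `step / Lp`, which
#' reproduces the 2-D tangent correlation `<cos theta(s)> = exp(-s/(2 Lp))`
#' and hence the closed-form mean squared end-to-end distance of
#' [wlc_msed()]. Contour lengths are drawn uniformly over `Lc_range`.
#' A fixed seed gives byte-identical output.
#'
#' @param n Number of fibrils.
#' @param Lp Persistence length in nm.
#' @param Lc_range Contour-length range in nm, `c(min, max)`.
#' @param step Segment length in nm.
#' @param seed Integer seed.
#' @return A tibble with columns `fibril_id`, `x_nm`, `y_nm`.
#' @examples
#' traces <- sim_wlc_contours(10, Lp = 200, Lc_range = c(100, 500), seed = 1)
#' @export
sim_wlc_contours <- function(n, Lp, Lc_range = c(100, 800), step = 5,
                             seed = 1) {
  if (Lp <= 0 || step <= 0 || n < 1) abort("n, Lp and step must be positive")
  .with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      Lc <- runif(1, Lc_range[1], Lc_range[2])
      m <- max(ceiling(Lc / step), 2)
      turns <- rnorm(m - 1, 0, sqrt(step / Lp))
      ang <- cumsum(c(runif(1, 0, 2 * pi), turns))
      tibble(fibril_id = i,
             x_nm = cumsum(c(0, step * cos(ang))),
             y_nm = cumsum(c(0, step * sin(ang))))
    })
  })
}

#' Simulate SAXS profiles of a fibril dilution series
#'
#' Forward model: intensity proportional to concentration times the rigid
#' cylinder form factor, an optional Gaussian correlation peak in the
#' structure factor of every concentration above the most dilute member
#' (the dilute profile is form-factor only, `S = 1`), and multiplicative
#' log-normal noise emulating detector statistics.
#'
#' @param D,L Cylinder diameter and length in nm.
#' @param c_list Concentrations in wt%; the minimum is the dilute
#'   reference.
#' @param peak Optional `list(q0 = , amplitude = , width = )` in
#'   1/Angstrom describing the correlation peak.
#' @param noise Log-normal noise level (sdlog); 0 for noise-free.
#' @param q Momentum-transfer grid in 1/Angstrom.
#' @param seed Integer seed.
#' @return A tibble with columns `q`, `I`, `sigma`, `c_wt`, `label`;
#'   filter on `c_wt` to obtain single profiles.
#' @examples
#' prof <- sim_saxs_profiles(4, 380, c_list = c(1, 3),
#'                           peak = list(q0 = 0.03, amplitude = 0.6,
#'                                       width = 0.006), seed = 1)
#' @export
sim_saxs_profiles <- function(D, L, c_list, peak = NULL, noise = 0,
                              q = 10^seq(-2.6, -0.6, length.out = 200),
                              seed = 1) {
  if (any(c_list <= 0)) abort("concentrations must be positive")
  if (noise < 0) abort("noise must be >= 0")
  V <- pi * (D / 2)^2 * L
  P <- cylinder_form_factor(q, D, L, scale = 1 / V^2)
  c_ref <- min(c_list)
  .with_seed(seed, {
    purrr::map_dfr(c_list, function(cc) {
      S <- rep(1, length(q))
      if (!is.null(peak) && cc > c_ref) {
        S <- 1 + peak$amplitude * exp(-(q - peak$q0)^2 / (2 * peak$width^2))
      }
      I <- cc * P * S
      if (noise > 0) I <- I * exp(rnorm(length(q), 0, noise))
      tibble(q = q, I = I, sigma = pmax(noise, 0.01) * I, c_wt = cc,
             label = sprintf("%.2f wt%%", cc))
    })
  })
}

#' Simulate a FRAP trace
#'
#' Raw bleached-ROI, reference-ROI and background intensities whose
#' double-normalized trace follows `I = A (1 - exp(-t/tau)) + C` after the
#' bleach, with `C` the bleach depth. An exponential acquisition decay
#' (photobleaching during imaging) is applied to both ROIs, so it cancels
#' exactly under [normalize_frap()]. Gaussian acquisition noise is added
#' to both ROIs.
#'
#' @param A,C Recovery amplitude and bleach depth (normalized units).
#' @param tau Characteristic recovery time in s.
#' @param acq_decay Acquisition photobleaching rate in 1/s (common to both
#'   ROIs).
#' @param noise Gaussian noise sd on the normalized intensity (the
#'   observable the recovery model is fitted to); realized as noise on the
#'   small bleached ROI, the dominant stochastic channel, while the
#'   reference ROI and background vary only through the shared
#'   acquisition decay. The signal-to-noise ratio of the trace is
#'   `1/noise`.
#' @param n_frames Number of post-bleach frames. The default acquisition
#'   (0.25 s frames, 35 s of recovery) mirrors typical spinning-disk
#'   bleach-recovery protocols on tactoids.
#' @param n_pre Number of pre-bleach frames.
#' @param dt Frame interval in s.
#' @param omega Bleached-ROI radius in um (stored as an attribute).
#' @param seed Integer seed.
#' @return A tibble with columns `t`, `T1`, `T2`, `B`; attributes
#'   `bleach_index` and `omega`.
#' @examples
#' tr <- sim_frap_trace(A = 0.5, C = 0.3, tau = 5, noise = 0.01, seed = 1)
#' attr(tr, "bleach_index")
#' @export
sim_frap_trace <- function(A, C, tau, acq_decay = 0, noise = 0,
                           n_frames = 140, n_pre = 8, dt = 0.25,
                           omega = 1.5, seed = 1) {
  if (tau <= 0 || n_pre < 1 || n_frames < 10) {
    abort("tau must be > 0 with >= 1 pre-bleach and >= 10 post-bleach frames")
  }
  t <- seq(0, by = dt, length.out = n_pre + n_frames)
  bleach_index <- n_pre + 1
  tp <- t - t[bleach_index]
  ideal <- ifelse(tp < 0, 1, A * (1 - exp(-tp / tau)) + C)
  decay <- exp(-acq_decay * t)
  B0 <- 100; S1 <- 900; S2 <- 800
  .with_seed(seed, {
    T1 <- B0 + S1 * (ideal + rnorm(length(t), 0, noise)) * decay
    T2 <- B0 + S2 * decay
    out <- tibble(t = t, T1 = T1, T2 = T2, B = B0)
    attr(out, "bleach_index") <- bleach_index
    attr(out, "omega") <- omega
    out
  })
}

#' Simulate an electrophoretic mobility titration
#'
#' Forward electrokinetic model over a pH grid: the supplied charge curve
#' is converted per pH to a surface potential (inverting the nonlinear
#' Poisson-Boltzmann relation) and then to an orientation-averaged
#' mobility via the generalized Henry factors, plus Gaussian measurement
#' noise. The mobility changes sign where `lambda(pH)` crosses zero (the
#' isoelectric point).
#'
#' @param lambda_of_ph Function `lambda(pH)` in e/nm, or a data frame with
#'   columns `pH`, `lambda`.
#' @param D Fibril diameter in nm.
#' @param pH_grid pH values to sample.
#' @param noise Gaussian sd on the mobility, um cm / (V s).
#' @param config An [fp_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `pH`, `I` (mol/L), `mobility`, `sd`,
#'   `lambda_true`.
#' @export
sim_mobility_titration <- function(lambda_of_ph, D, pH_grid = 2:9,
                                   noise = 0, config = fp_config(),
                                   seed = 1) {
  lam_fn <- if (is.function(lambda_of_ph)) lambda_of_ph else
    smooth_charge_vs_ph(lambda_of_ph)
  .with_seed(seed, {
    purrr::map_dfr(pH_grid, function(pH) {
      cond <- solution_conditions(pH, config$temperature, config$eps_r)
      lambda <- lam_fn(pH)
      psi0 <- .linear_charge_to_surface_potential(lambda, D, cond)
      mob <- .surface_potential_to_mobility(psi0, D, cond,
                                            viscosity = config$viscosity)
      tibble(pH = pH, I = cond$I_nom,
             mobility = mob + rnorm(1, 0, noise), sd = noise,
             lambda_true = lambda)
    })
  })
}

#' Simulate phase observations over a (pH, concentration) grid
#'
#' Labels each grid point isotropic / liquid-crystalline / liquid-liquid
#' using the forward threshold model at the supplied per-pH charge and
#' internal ionic strength, with an optional multiplicative jitter on the
#' observed threshold emulating the experimental observation window. The
#' generating thresholds are attached as the `"thresholds"` attribute;
#' [extract_start_concentrations()] recovers bracketing start
#' concentrations from the labels alone.
#'
#' @param geom A [fibril_geometry()].
#' @param lambda_of_ph Function or table of `lambda(pH)` in e/nm.
#' @param I_in_of_ph Function or table (`pH`, `I_in`) of internal ionic
#'   strength in mol/L.
#' @param pH_grid pH values.
#' @param c_grid Concentration grid in wt%.
#' @param jitter Half-width of the uniform multiplicative jitter on the
#'   observed threshold (0 = none).
#' @param config An [fp_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `pH`, `c_wt`, `regime`; attribute
#'   `thresholds` is a tibble (`pH`, `lambda`, `I_in`, `c_IN`).
#' @export
sim_phase_observations <- function(geom, lambda_of_ph, I_in_of_ph,
                                   pH_grid = 2:7,
                                   c_grid = seq(0.2, 3, by = 0.2),
                                   jitter = 0, config = fp_config(),
                                   seed = 1) {
  lam_fn <- if (is.function(lambda_of_ph)) lambda_of_ph else
    smooth_charge_vs_ph(lambda_of_ph)
  iin_fn <- if (is.function(I_in_of_ph)) I_in_of_ph else
    splinefun(I_in_of_ph$pH, I_in_of_ph$I_in, method = "monoH.FC")
  .with_seed(seed, {
    thr <- purrr::map_dfr(pH_grid, function(pH) {
      lambda <- lam_fn(pH)
      cond <- solution_conditions(pH, config$temperature, config$eps_r,
                                  I_in = max(iin_fn(pH),
                                             nominal_ionic_strength(pH)))
      pred <- predict_threshold_concentration(geom, lambda, cond, config)
      tibble(pH = pH, lambda = lambda, I_in = cond$I_in,
             c_IN = pred$c_IN_wt)
    })
    obs <- purrr::map_dfr(seq_len(nrow(thr)), function(i) {
      c_thr <- thr$c_IN[i] * (1 + jitter * runif(1, -1, 1))
      tibble(pH = thr$pH[i], c_wt = c_grid,
             regime = classify_regime(thr$lambda[i], c_grid, c_thr,
                                      config$lambda_llps))
    })
    attr(obs, "thresholds") <- thr
    obs
  })
}

#' Extract start concentrations from labelled phase observations
#'
#' Per pH, the minimum concentration labelled non-isotropic (`c_min`) and
#' the midpoint of the bracketing observation window (`c_mean`): together
#' they bracket the generating threshold to the grid resolution.
#'
#' @param obs Output of [sim_phase_observations()] (columns `pH`, `c_wt`,
#'   `regime`).
#' @return A tibble with columns `pH`, `c_mean`, `c_min`, `regime_label`.
#' @export
extract_start_concentrations <- function(obs) {
  if (!all(c("pH", "c_wt", "regime") %in% names(obs))) {
    abort("obs must have columns pH, c_wt, regime")
  }
  dplyr::summarise(
    dplyr::group_by(as_tibble(obs), .data$pH),
    c_min = {
      dem <- .data$c_wt[.data$regime != "isotropic"]
      if (length(dem) == 0) NA_real_ else min(dem)
    },
    c_below = {
      dem <- .data$c_wt[.data$regime != "isotropic"]
      iso <- if (length(dem) == 0) .data$c_wt else
        .data$c_wt[.data$c_wt < min(dem)]
      if (length(iso) == 0) NA_real_ else max(iso)
    },
    regime_label = {
      dem <- .data$regime[.data$regime != "isotropic"]
      if (length(dem) == 0) "isotropic" else dem[1]
    },
    .groups = "drop") |>
    dplyr::mutate(c_mean = (.data$c_min + .data$c_below) / 2) |>
    dplyr::select("pH", "c_mean", "c_min", "regime_label")
}
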