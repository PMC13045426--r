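# fixed Gauss-Legendre rule for the orientation average, built once
.gl_cache <- new.env(parent = emptyenv())
.gl_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, pi / 2)
  }
  .gl_cache[[key]]
}

# sin(z)/z and 2 J1(z)/z with stable small-argument limits
.sinc <- function(z) ifelse(abs(z) < 1e-8, 1, sin(z) / z)
.j1c <- function(z) ifelse(abs(z) < 1e-8, 1, 2 * besselJ(z, 1) / z)

#' Orientation-averaged rigid-cylinder form factor
#'
#' Scattered intensity of randomly oriented rigid cylinders,
#' `P(q) = scale * int_0^{pi/2} A(q, alpha)^2 sin(alpha) dalpha + background`
#' with amplitude
#' `A = V [2 J1(q R sin a) / (q R sin a)] [sin(q L cos a / 2) / (q L cos a / 2)]`,
#' evaluated by fixed-node Gauss-Legendre quadrature over the rod
#' orientation. At `q -> 0` the (background-subtracted) intensity tends to
#' `scale * V^2`; for `L >> D` the intermediate-q envelope decays as `1/q`.
#'
#' @param q Momentum transfer in 1/Angstrom.
#' @param D Cylinder diameter in nm.
#' @param L Cylinder length in nm.
#' @param scale Multiplicative scale (absorbs contrast and number density).
#' @param background Flat background added to the intensity.
#' @param n_alpha Number of quadrature nodes.
#' @return Intensity (arbitrary units), same length as `q`.
#' @examples
#' q <- 10^seq(-2.5, -0.5, length.out = 50)
#' I <- cylinder_form_factor(q, D = 4, L = 380)
#' @export
cylinder_form_factor <- function(q, D, L, scale = 1, background = 0,
                                 n_alpha = 128) {
  if (D <= 0 || L <= 0) abort("D and L must be positive")
  rule <- .gl_rule(n_alpha)
  q_nm <- q * 10                      # 1/Angstrom -> 1/nm
  R <- D / 2
  V <- pi * R^2 * L
  qa <- outer(q_nm, sin(rule$x))      # q R sin(alpha) pieces
  amp <- .j1c(qa * R) * .sinc(outer(q_nm, cos(rule$x)) * L / 2)
  integrand <- amp^2 * matrix(sin(rule$x), nrow = length(q_nm),
                              ncol = n_alpha, byrow = TRUE)
  scale * V^2 * as.vector(integrand %*% rule$w) + background
}

# Deterministic (D, L) grid profiling: at each node, scale and background
# are the weighted linear least-squares solution, so only the two
# nonlinear parameters are scanned. Returns the most promising mutually
# distinct nodes as multistart candidates for the nonlinear polish.
.ff_grid_start <- function(df, wts, D0 = NULL, L0 = NULL, n_starts = 6) {
  rss_at <- function(D, L) {
    P <- cylinder_form_factor(df$q, D, L)
    fit <- stats::lm.wfit(cbind(P, 1), df$I, wts)
    cf <- fit$coefficients
    list(rss = sum(wts * fit$residuals^2), D = D, L = L,
         scale = cf[1], background = max(cf[2], 0))
  }
  D_cands <- if (is.null(D0)) seq(1.5, 12, by = 0.5) else D0
  L_cands <- if (is.null(L0)) 10^seq(log10(20), log10(3000),
                                     length.out = 40) else L0
  nodes <- purrr::map(D_cands, function(D) purrr::map(L_cands, rss_at, D = D))
  nodes <- purrr::flatten(nodes)
  nodes <- nodes[order(vapply(nodes, `[[`, numeric(1), "rss"))]
  picked <- list()
  for (nd in nodes) {
    distinct <- all(vapply(picked, function(p) {
      abs(log(p$D / nd$D)) > 0.1 || abs(log(p$L / nd$L)) > 0.1
    }, logical(1)))
    if (length(picked) == 0 || distinct) picked <- c(picked, list(nd))
    if (length(picked) >= n_starts) break
  }
  picked
}

#' Fit a cylinder form factor to a SAXS profile
#'
#' Weighted nonlinear least squares of the orientation-averaged cylinder
#' model over diameter, length, scale and flat background
#' (Levenberg-Marquardt). Weights are `1/sigma^2` when an uncertainty
#' column is present, else uniform relative weights `1/I^2`. Deterministic
#' given the data and starting values.
#'
#' The optimization surface is multi-modal in `L` (the orientation
#' average only partly washes out the length oscillations), so when no
#' starting length is supplied the fit first profiles a deterministic
#' `(D, L)` grid — with scale and background refit linearly at every node
#' — and polishes the best node by Levenberg-Marquardt.
#'
#' @param profile A data frame with columns `q` (1/Angstrom, ascending),
#'   `I`, and optionally `sigma`; at least 30 points.
#' @param init Optional named list of starting values `D`, `L`, `scale`,
#'   `background`; values given here bypass the corresponding grid stage.
#' @return An object of class `"fp_saxs_fit"`: a list with elements `D`,
#'   `L`, `scale`, `background` (fitted values), `goodness` (reduced
#'   chi-square), `fit` (the underlying `nls` object) and `profile`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' prof <- sim_saxs_profiles(D = 4, L = 380, c_list = 1, seed = 1)
#' fit <- fit_form_factor(prof)
#' glance(fit)
#' @export
fit_form_factor <- function(profile, init = NULL) {
  if (!all(c("q", "I") %in% names(profile))) {
    abort("profile must have columns q and I")
  }
  if (nrow(profile) < 30) {
    abort("at least 30 q-points are required to constrain the fit")
  }
  if (is.unsorted(profile$q, strictly = TRUE) || any(profile$q <= 0)) {
    abort("q must be positive and strictly ascending")
  }
  wts <- if ("sigma" %in% names(profile) && all(profile$sigma > 0)) {
    1 / profile$sigma^2
  } else {
    1 / profile$I^2
  }
  df <- data.frame(q = profile$q, I = profile$I)
  starts <- if (is.null(init$D) || is.null(init$L)) {
    .ff_grid_start(df, wts, D0 = init$D, L0 = init$L)
  } else {
    list(init)
  }
  polish <- function(st) {
    s0 <- init$scale %||% st$scale %||%
      (df$I[1] / cylinder_form_factor(df$q[1], st$D, st$L))
    bg0 <- init$background %||% st$background %||% 0
    if (!is.finite(s0) || s0 <= 0) {
      s0 <- df$I[1] / cylinder_form_factor(df$q[1], st$D, st$L)
      bg0 <- 0
    }
    minpack.lm::nlsLM(
      I ~ cylinder_form_factor(q, D, L, exp(log_scale), background),
      data = df,
      start = list(D = st$D, L = st$L, log_scale = log(s0),
                   background = bg0),
      weights = wts,
      lower = c(0.1, 1, -Inf, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))
  }
  fits <- purrr::map(starts, function(st) {
    tryCatch(polish(st), error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    abort("form-factor fit did not converge from any starting point")
  }
  fit <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  # the deviance surface is finely corrugated along L; profile L once
  # around the polished solution (scale and background refit linearly)
  # and re-polish if a better node turns up
  for (pass in 1:2) {
    cf <- coef(fit)
    Lf <- unname(cf["L"])
    nodes <- .ff_grid_start(df, wts, D0 = unname(cf["D"]),
                            L0 = seq(max(Lf - 5, 1), Lf + 5, by = 0.1),
                            n_starts = 1)
    cand <- tryCatch(polish(nodes[[1]]), error = function(e) NULL)
    if (is.null(cand) || stats::deviance(cand) >= stats::deviance(fit)) break
    fit <- cand
  }
  cf <- coef(fit)
  res <- summary(fit)$residuals
  structure(
    list(D = unname(cf["D"]), L = unname(cf["L"]),
         scale = exp(unname(cf["log_scale"])),
         background = unname(cf["background"]),
         goodness = sum(res^2) / (nrow(df) - 4),
         fit = fit, profile = as_tibble(profile)),
    class = "fp_saxs_fit")
}

#' @export
print.fp_saxs_fit <- function(x, ...) {
  cat(sprintf(
    "<fp_saxs_fit> D = %.2f nm, L = %.0f nm, background = %.3g, reduced chi^2 = %.3g\n",
    x$D, x$L, x$background, x$goodness))
  invisible(x)
}

#' Structure factor from a dense and a dilute reference profile
#'
#' `S(q) = I_dense(q) / (N_ratio * I_ref(q))`: inter-particle correlations
#' isolated by dividing the dense-sample intensity by the form factor
#' estimated from a dilute isotropic reference, scaled by the fibril number
#' density ratio. The dense profile is interpolated onto the reference
#' grid; a dense sample that is a pure concentration rescale of the
#' reference yields `S = 1` identically.
#'
#' @param dense A data frame with columns `q`, `I` (the concentrated
#'   sample).
#' @param reference A data frame with columns `q`, `I` (dilute isotropic
#'   sample, form-factor only).
#' @param N_ratio Number-density ratio dense/reference (e.g. the
#'   concentration ratio).
#' @return A tibble with class `"fp_structure_factor"`: columns `q`, `S`.
#' @examples
#' ref <- sim_saxs_profiles(D = 4, L = 380, c_list = 1, seed = 1)
#' dense <- dplyr::mutate(ref, I = 2 * I)
#' sf <- structure_factor(dense, ref, N_ratio = 2)
#' all.equal(sf$S, rep(1, nrow(sf)))
#' @export
structure_factor <- function(dense, reference, N_ratio) {
  for (nm in list(dense, reference)) {
    if (!all(c("q", "I") %in% names(nm))) {
      abort("profiles must have columns q and I")
    }
  }
  if (N_ratio <= 0) abort("N_ratio must be > 0")
  if (min(reference$q) < min(dense$q) || max(reference$q) > max(dense$q)) {
    abort("reference q grid extends beyond the dense profile: cannot interpolate")
  }
  I_d <- approx(dense$q, dense$I, xout = reference$q)$y
  out <- tibble(q = reference$q, S = I_d / (N_ratio * reference$I))
  class(out) <- c("fp_structure_factor", class(out))
  out
}

#' Locate the structure-factor correlation peak
#'
#' Fits a smoothing spline to `S(q)` inside the search window and returns
#' the analytic maximum of the interpolant. Errors when `S` has no
#' interior maximum in the window (monotone structure factor).
#'
#' @param sf A structure factor from [structure_factor()] (or any data
#'   frame with columns `q`, `S`).
#' @param q_window Search window in 1/Angstrom; the default brackets the
#'   intermediate-q range where fibril correlation peaks appear.
#' @param spar Smoothing parameter passed to [smooth.spline()].
#' @return Peak position `q*` in 1/Angstrom.
#' @export
find_sf_peak <- function(sf, q_window = c(0.01, 0.04), spar = 0.5) {
  if (!all(c("q", "S") %in% names(sf))) abort("sf must have columns q and S")
  inside <- sf$q >= q_window[1] & sf$q <= q_window[2]
  if (sum(inside) < 8) abort("search window contains fewer than 8 grid points")
  qs <- sf$q[inside]
  Ss <- sf$S[inside]
  if (diff(range(Ss)) < 1e-9 * max(1, abs(mean(Ss)))) {
    abort("no interior peak: S(q) is flat over the search window")
  }
  sp <- smooth.spline(qs, Ss, spar = spar)
  opt <- optimize(function(q) predict(sp, q)$y,
                  interval = range(qs), maximum = TRUE)
  edge <- min(opt$maximum - min(qs), max(qs) - opt$maximum)
  prominence <- opt$objective - max(predict(sp, range(qs))$y)
  if (edge < diff(range(qs)) * 1e-3 ||
      prominence < 1e-8 * max(1, abs(opt$objective))) {
    abort("no interior peak: S(q) is monotone over the search window")
  }
  opt$maximum
}

#' Real-space periodicity from a correlation-peak position
#'
#' `d = 2 pi / q*`, converted from Angstrom to nm.
#'
#' @param q_star Peak position in 1/Angstrom.
#' @return Periodicity (inter-fibril spacing) in nm.
#' @examples
#' spacing_from_peak(0.03) # ~20.9 nm
#' @export
spacing_from_peak <- function(q_star) {
  if (any(q_star <= 0)) abort("q_star must be > 0")
  2 * pi / q_star / 10
}
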