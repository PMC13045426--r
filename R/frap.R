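#' Double-normalize a FRAP trace
#'
#' Normalizes the bleached-ROI intensity against a reference ROI so that
#' any acquisition photobleaching common to both regions cancels exactly:
#' `I_t = [(T1_t - B_t)/(T1_0 - B_0)] / [(T2_t - B_t)/(T2_0 - B_0)]`,
#' where frame 0 is the last pre-bleach frame, so `I_0 = 1` by
#' construction and the bleach depth is the first post-bleach value.
#'
#' @param trace A data frame with columns `t` (s, ascending), `T1`
#'   (bleached ROI), `T2` (reference ROI), `B` (background).
#' @param bleach_index Index (1-based) of the first post-bleach frame; the
#'   reference frame is `bleach_index - 1`.
#' @return The input as a tibble with an added column `I` (normalized
#'   intensity).
#' @export
normalize_frap <- function(trace, bleach_index) {
  req <- c("t", "T1", "T2", "B")
  if (!all(req %in% names(trace))) {
    abort(paste0("trace must have columns ", paste(req, collapse = ", ")))
  }
  if (bleach_index < 2 || bleach_index > nrow(trace)) {
    abort("bleach_index must point inside the trace, after at least one pre-bleach frame")
  }
  if (is.unsorted(trace$t, strictly = TRUE)) abort("t must be strictly ascending")
  i0 <- bleach_index - 1
  d1 <- trace$T1 - trace$B
  d2 <- trace$T2 - trace$B
  if (d1[i0] == 0 || d2[i0] == 0 || any(d2 == 0)) {
    abort("degenerate trace: zero background-corrected intensity in the normalization")
  }
  out <- as_tibble(trace)
  out$I <- (d1 / d1[i0]) / (d2 / d2[i0])
  out
}

#' Fit a single-exponential recovery to a normalized FRAP trace
#'
#' Nonlinear least squares of `I_t = A (1 - exp(-t/tau)) + C` over the
#' post-bleach frames only, with time re-zeroed at the first post-bleach
#' frame. Starting values come from the curve endpoints, so the fit is
#' deterministic given the data. The plateau is `I_inf = A + C` and the
#' bleach depth `I_bl = C`, both taken from the fit rather than from
#' single (noisy) frames; the mobile fraction is
#' `(I_inf - I_bl) / (I_0 - I_bl)` with `I_0` the pre-bleach level (1 for
#' a normalized trace), which reduces to `A / (1 - C)`.
#'
#' @param trace A normalized trace from [normalize_frap()] (columns `t`,
#'   `I`), or any data frame with those columns.
#' @param bleach_index Index of the first post-bleach frame.
#' @param omega Bleached-ROI radius in um (used for the apparent diffusion
#'   coefficient); `NA` omits it.
#' @return An object of class `"fp_frap_fit"`: `A`, `C`, `tau` (s),
#'   `tau_half` (s), `D_app` (um^2/s, `NA` without `omega`),
#'   `mobile_fraction`, `I_inf`, `fit` (the `nls` object) and `data`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' tr <- sim_frap_trace(A = 0.5, C = 0.3, tau = 5, seed = 1)
#' fit <- fit_frap_recovery(normalize_frap(tr, attr(tr, "bleach_index")),
#'                          attr(tr, "bleach_index"), omega = 1.5)
#' tidy(fit)
#' @export
fit_frap_recovery <- function(trace, bleach_index, omega = NA_real_) {
  if (!all(c("t", "I") %in% names(trace))) {
    abort("trace must have columns t and I (run normalize_frap first)")
  }
  post <- seq(bleach_index, nrow(trace))
  if (length(post) < 10) abort("at least 10 post-bleach frames are required")
  tp <- trace$t[post] - trace$t[bleach_index]
  Ip <- trace$I[post]
  if (diff(range(Ip)) < sqrt(.Machine$double.eps)) {
    abort("degenerate input: constant post-bleach intensity, recovery time unbounded")
  }
  C0 <- mean(utils::head(Ip, 3))
  A0 <- max(mean(utils::tail(Ip, 5)) - C0, 0.05)
  tau0 <- max(tp[length(tp)] / 3, diff(tp[1:2]))
  df <- data.frame(t = tp, I = Ip)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ A * (1 - exp(-t / tau)) + C, data = df,
                      start = list(A = A0, C = C0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("recovery fit failed: ",
                                     conditionMessage(e))))
  cf <- as.list(coef(fit))
  I_inf <- cf$A + cf$C
  mob <- mobile_fraction(I_inf, I_bl = cf$C, I_0 = 1)
  structure(
    list(A = cf$A, C = cf$C, tau = cf$tau,
         tau_half = cf$tau * log(2),
         D_app = if (is.na(omega)) NA_real_ else
           frap_metrics(cf$tau, omega)$D_app,
         mobile_fraction = mob, I_inf = I_inf, omega = omega,
         fit = fit, data = tibble(t = tp, I = Ip)),
    class = "fp_frap_fit")
}

#' @export
print.fp_frap_fit <- function(x, ...) {
  cat(sprintf(
    "<fp_frap_fit> tau = %.3g s (tau_half = %.3g s), mobile fraction = %.2f",
    x$tau, x$tau_half, x$mobile_fraction))
  if (!is.na(x$D_app)) cat(sprintf(", D_app = %.3g um^2/s", x$D_app))
  cat("\n")
  invisible(x)
}

#' Recovery half-time and apparent diffusion coefficient
#'
#' `tau_half = tau ln 2` and `D_app = 0.88 omega^2 / (4 tau_half)` for a
#' circular bleach region of radius `omega`.
#'
#' @param tau Characteristic recovery time in s.
#' @param omega Bleached-ROI radius in um.
#' @return A list with `tau_half` (s) and `D_app` (um^2/s).
#' @examples
#' frap_metrics(5, omega = 1.5)
#' @export
frap_metrics <- function(tau, omega) {
  if (any(tau <= 0) || any(omega <= 0)) abort("tau and omega must be > 0")
  tau_half <- tau * log(2)
  list(tau_half = tau_half, D_app = 0.88 * omega^2 / (4 * tau_half))
}

#' Mobile fraction of a bleach-recovery experiment
#'
#' `(I_inf - I_bl) / (I_0 - I_bl)`: 1 for full recovery, 0 for none.
#'
#' @param I_inf Normalized intensity after full recovery (fit plateau).
#' @param I_bl Normalized intensity immediately after bleaching.
#' @param I_0 Normalized intensity before bleaching.
#' @return Dimensionless fraction.
#' @examples
#' mobile_fraction(0.8, 0.2, 1.0) # 0.75
#' @export
mobile_fraction <- function(I_inf, I_bl, I_0) {
  if (any(I_0 == I_bl)) {
    abort("degenerate trace: pre-bleach and post-bleach intensities are equal")
  }
  (I_inf - I_bl) / (I_0 - I_bl)
}
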