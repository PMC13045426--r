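#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per model parameter
#' with standard errors from the underlying least-squares fit; `glance()`
#' returns a one-row model summary.
#'
#' @param x A fitted object (`fp_saxs_fit`, `fp_frap_fit`, `fp_wlc_fit`).
#' @param ... Unused.
#' @return A tibble.
#' @name fp_tidiers
NULL

.nls_tidy <- function(fit, rename = identity) {
  sm <- summary(fit)$coefficients
  tibble(term = rename(rownames(sm)),
         estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"])
}

#' @rdname fp_tidiers
#' @method tidy fp_saxs_fit
#' @export
tidy.fp_saxs_fit <- function(x, ...) {
  out <- .nls_tidy(x$fit)
  # report scale on the natural scale (delta method for the s.e.)
  i <- out$term == "log_scale"
  out$std.error[i] <- out$std.error[i] * exp(out$estimate[i])
  out$estimate[i] <- exp(out$estimate[i])
  out$term[i] <- "scale"
  out$unit <- c(D = "nm", L = "nm", scale = "", background = "I")[out$term]
  out
}

#' @rdname fp_tidiers
#' @method glance fp_saxs_fit
#' @export
glance.fp_saxs_fit <- function(x, ...) {
  tibble(D_nm = x$D, L_nm = x$L, scale = x$scale,
         background = x$background, reduced_chisq = x$goodness,
         n = nrow(x$profile))
}

#' @rdname fp_tidiers
#' @method tidy fp_frap_fit
#' @export
tidy.fp_frap_fit <- function(x, ...) {
  out <- .nls_tidy(x$fit)
  out$unit <- c(A = "", C = "", tau = "s")[out$term]
  out
}

#' @rdname fp_tidiers
#' @method glance fp_frap_fit
#' @export
glance.fp_frap_fit <- function(x, ...) {
  tibble(tau_s = x$tau, tau_half_s = x$tau_half,
         D_app_um2_s = x$D_app, mobile_fraction = x$mobile_fraction,
         I_inf = x$I_inf, n = nrow(x$data))
}

#' @rdname fp_tidiers
#' @method tidy fp_wlc_fit
#' @export
tidy.fp_wlc_fit <- function(x, ...) {
  tibble(term = "Lp", estimate = x$Lp,
         conf.low = x$ci[1], conf.high = x$ci[2], unit = "nm")
}

#' @rdname fp_tidiers
#' @method glance fp_wlc_fit
#' @export
glance.fp_wlc_fit <- function(x, ...) {
  tibble(Lp_nm = x$Lp, ci_low_nm = x$ci[1], ci_high_nm = x$ci[2],
         rigid_limit_flag = x$rigid_limit_flag,
         n_fibrils = nrow(x$per_fibril),
         mean_Lc_nm = mean(x$per_fibril$Lc))
}
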