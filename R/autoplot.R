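#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects for the main result
#' types: pair-potential curves (both orientation branches), structure
#' factors with the located peak, form-factor and recovery fits with the
#' fitted curve overlaid, worm-like-chain fits, and assembled phase
#' diagrams.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fp_autoplot
NULL

#' @rdname fp_autoplot
#' @method autoplot fp_pair_curve
#' @export
autoplot.fp_pair_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object,
    cols = c("U_el_par", "U_el_perp", "U_vdW_par", "U_vdW_perp",
             "U_tot_par", "U_tot_perp"),
    names_to = c("component", "orientation"),
    names_pattern = "U_(el|vdW|tot)_(par|perp)",
    values_to = "U_kT")
  ggplot2::ggplot(long, ggplot2::aes(.data$x_over_D, .data$U_kT,
                                     colour = .data$component,
                                     linetype = .data$orientation)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x / D", y = "U (kT)", colour = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fp_autoplot
#' @method autoplot fp_structure_factor
#' @export
autoplot.fp_structure_factor <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$q, .data$S)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "S(q)") +
    ggplot2::theme_minimal()
  peak <- tryCatch(find_sf_peak(object), error = function(e) NULL)
  if (!is.null(peak)) {
    p <- p + ggplot2::geom_vline(xintercept = peak, linetype = 3,
                                 colour = "red")
  }
  p
}

#' @rdname fp_autoplot
#' @method autoplot fp_saxs_fit
#' @export
autoplot.fp_saxs_fit <- function(object, ...) {
  prof <- object$profile
  prof$fitted <- cylinder_form_factor(prof$q, object$D, object$L,
                                      object$scale, object$background)
  ggplot2::ggplot(prof, ggplot2::aes(.data$q, .data$I)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)") +
    ggplot2::theme_minimal()
}

#' @rdname fp_autoplot
#' @method autoplot fp_frap_fit
#' @export
autoplot.fp_frap_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$A * (1 - exp(-d$t / object$tau)) + object$C
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$I)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time after bleach (s)",
                  y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' @rdname fp_autoplot
#' @method autoplot fp_wlc_fit
#' @export
autoplot.fp_wlc_fit <- function(object, ...) {
  grid <- tibble(Lc = seq(min(object$per_fibril$Lc),
                          max(object$per_fibril$Lc), length.out = 200))
  grid$R2 <- wlc_msed(grid$Lc, object$Lp, object$convention)
  ggplot2::ggplot(object$per_fibril, ggplot2::aes(.data$Lc, .data$R2)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.4) +
    ggplot2::geom_point(data = object$binned, colour = "blue", size = 2) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = expression(L[c] ~ (nm)),
                  y = expression(bgroup("<", R^2, ">") ~ (nm^2))) +
    ggplot2::theme_minimal()
}

#' @rdname fp_autoplot
#' @method autoplot fp_phase_diagram
#' @export
autoplot.fp_phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pH)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$c_IN_wt),
                       colour = "grey40", linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$c_mean,
                                     colour = .data$regime), size = 2) +
    ggplot2::labs(y = "concentration (wt %)", colour = "regime") +
    ggplot2::theme_minimal()
}
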