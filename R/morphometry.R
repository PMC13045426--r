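#' Contour length of a traced fibril
#'
#' Polyline arc length of an ordered 2-D trace; always at least the
#' end-to-end distance.
#'
#' @param points A two-column matrix or data frame of ordered `(x, y)`
#'   coordinates in nm.
#' @return Contour length in nm.
#' @export
contour_length <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2) abort("a contour needs at least 2 points")
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Squared end-to-end distance of a traced fibril
#'
#' @inheritParams contour_length
#' @return Squared end-to-end distance in nm^2.
#' @export
end_to_end_sq <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2) abort("a contour needs at least 2 points")
  sum((pts[nrow(pts), ] - pts[1, ])^2)
}

#' Worm-like-chain mean squared end-to-end distance (2-D)
#'
#' Closed form for a chain equilibrated in two dimensions (the geometry of
#' fibrils adsorbed flat on mica before imaging):
#' `<R^2> = 4 Lp Lc [1 - (2 Lp / Lc)(1 - exp(-Lc / (2 Lp)))]`.
#' Tends to `Lc^2` in the rigid limit and to `4 Lp Lc` in the flexible
#' limit. The 3-D-projected convention (`2 Lp Lc [...]` with decay length
#' `Lp`) is available behind the `convention` flag.
#'
#' @param Lc Contour length in nm.
#' @param Lp Persistence length in nm.
#' @param convention `"2d"` (equilibrated on the surface, default) or
#'   `"3d"` (projected three-dimensional chain).
#' @return Mean squared end-to-end distance in nm^2.
#' @examples
#' wlc_msed(200, 200) / 200^2 # 0.852
#' @export
wlc_msed <- function(Lc, Lp, convention = c("2d", "3d")) {
  convention <- match.arg(convention)
  if (any(Lc <= 0) || any(Lp <= 0)) abort("Lc and Lp must be positive")
  xi <- switch(convention, "2d" = 2 * Lp, "3d" = Lp)
  2 * xi * Lc * (1 - (xi / Lc) * (1 - exp(-Lc / xi)))
}

#' Persistence length from traced contours
#'
#' Estimates the persistence length by weighted least squares of the
#' worm-like-chain closed form to the mean squared end-to-end distance as
#' a function of contour length. Traces are binned by contour length, the
#' per-bin mean `R^2` is fitted with weights `n_bin / var_bin`, and a
#' bootstrap over fibrils yields a confidence interval. Fibrils much
#' stiffer than their length drive the estimate toward the rigid limit;
#' when the fitted `Lp` exceeds the longest contour several-fold, a
#' divergence flag is set (the data then only bound `Lp` from below).
#'
#' @param traces A data frame with columns `fibril_id`, `x_nm`, `y_nm`
#'   (ordered vertices per fibril), or a list of two-column point
#'   matrices.
#' @param n_bins Number of contour-length bins.
#' @param n_boot Bootstrap replicates for the confidence interval (0
#'   disables).
#' @param convention Passed to [wlc_msed()].
#' @param conf_level Confidence level for the bootstrap interval.
#' @return An object of class `"fp_wlc_fit"`: `Lp` (nm), `ci` (nm),
#'   `rigid_limit_flag`, `per_fibril` (tibble of `Lc`, `R2`), `binned`
#'   (tibble used in the fit), `fit`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' traces <- sim_wlc_contours(n = 100, Lp = 200, Lc_range = c(100, 800),
#'                            seed = 1)
#' fit <- fit_persistence_length(traces, n_boot = 20)
#' glance(fit)
#' @export
fit_persistence_length <- function(traces, n_bins = 10, n_boot = 200,
                                   convention = "2d", conf_level = 0.95) {
  per <- .per_fibril_stats(traces)
  if (nrow(per) < 20) abort("at least 20 traces are required")
  ill <- FALSE
  if (diff(range(per$Lc)) < 1e-9 * mean(per$Lc)) {
    warn("all traces share one contour length: the fit is ill-conditioned; point estimate only")
    ill <- TRUE
  }
  est <- function(d) .wlc_point_estimate(d, n_bins, convention)
  point <- est(per)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && !ill) {
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(per), replace = TRUE)
      tryCatch(est(per[idx, ])$Lp, error = function(e) NA_real_)
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(
    list(Lp = point$Lp, ci = ci,
         rigid_limit_flag = point$Lp > 5 * max(per$Lc),
         per_fibril = per, binned = point$binned, fit = point$fit,
         convention = convention),
    class = "fp_wlc_fit")
}

#' @export
print.fp_wlc_fit <- function(x, ...) {
  cat(sprintf("<fp_wlc_fit> Lp = %.1f nm", x$Lp))
  if (!anyNA(x$ci)) cat(sprintf(" (CI %.1f - %.1f)", x$ci[1], x$ci[2]))
  if (x$rigid_limit_flag) {
    cat("  [rigid limit: Lp >> Lc, estimate is a lower bound]")
  }
  cat("\n")
  invisible(x)
}

.per_fibril_stats <- function(traces) {
  if (is.data.frame(traces)) {
    req <- c("fibril_id", "x_nm", "y_nm")
    if (!all(req %in% names(traces))) {
      abort(paste0("traces must have columns ", paste(req, collapse = ", ")))
    }
    split_pts <- split(traces[, c("x_nm", "y_nm")], traces$fibril_id)
  } else {
    split_pts <- traces
  }
  tibble(
    Lc = vapply(split_pts, contour_length, numeric(1)),
    R2 = vapply(split_pts, end_to_end_sq, numeric(1)))
}

.wlc_point_estimate <- function(per, n_bins, convention) {
  brk <- seq(min(per$Lc), max(per$Lc), length.out = n_bins + 1)
  brk[1] <- brk[1] - 1e-9
  bin <- cut(per$Lc, brk)
  binned <- dplyr::summarise(
    dplyr::group_by(tibble(bin = bin, Lc = per$Lc, R2 = per$R2), .data$bin),
    n = dplyr::n(), v = stats::var(.data$R2),
    Lc = mean(.data$Lc), R2 = mean(.data$R2), .groups = "drop")
  binned <- binned[binned$n >= 2 & binned$v > 0, ]
  if (nrow(binned) < 3) {
    # too sparse to bin: fit the raw points, uniform relative weights
    binned <- tibble(Lc = per$Lc, R2 = per$R2, n = 1, v = per$R2^2)
  }
  w <- binned$n / binned$v
  Lp0 <- mean(binned$R2 / (4 * binned$Lc))
  fit <- minpack.lm::nlsLM(
    R2 ~ wlc_msed(Lc, Lp, convention),
    data = as.data.frame(binned[, c("Lc", "R2")]),
    start = list(Lp = max(Lp0, 1)), weights = w,
    lower = 1e-3,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  list(Lp = unname(coef(fit)["Lp"]), binned = binned, fit = fit)
}
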