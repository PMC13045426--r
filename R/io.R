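#' Readers and writers for the pipeline file formats
#'
#' All tables are plain CSV with header rows and units embedded in the
#' column names; SAXS profiles additionally accept whitespace-separated
#' 3-column text.
#'
#' * mobility tables: `pH, ionic_strength_mM, mobility_umcmVs, sd`
#' * SAXS profiles: `q_Angstrom_inv, I, sigma` (sigma optional)
#' * FRAP traces: `t_s, T1, T2, B`
#' * contour traces: `fibril_id, x_nm, y_nm`
#' * phase observations: `pH, c_wt_percent, regime_label`
#'
#' @param path File path.
#' @return A tibble in the column convention of the consuming module.
#' @name fp_io
NULL

.require_cols <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing required column(s) %s", what,
                  paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

#' @rdname fp_io
#' @export
read_mobility_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .require_cols(df, c("pH", "ionic_strength_mM", "mobility_umcmVs"),
                "mobility table")
  out <- tibble(pH = df$pH, I = df$ionic_strength_mM / 1e3,
                mobility = df$mobility_umcmVs)
  if ("sd" %in% names(df)) out$sd <- df$sd
  out
}

#' @rdname fp_io
#' @export
read_saxs_profile <- function(path) {
  first <- readLines(path, n = 1)
  df <- if (grepl(",", first)) {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    readr::read_table(path, show_col_types = FALSE,
                      col_names = c("q_Angstrom_inv", "I", "sigma")[
                        seq_len(length(strsplit(trimws(first), "\\s+")[[1]]))])
  }
  names(df)[1] <- "q"
  if ("q_Angstrom_inv" %in% names(df)) names(df)[names(df) == "q_Angstrom_inv"] <- "q"
  .require_cols(df, c("q", "I"), "SAXS profile")
  if (any(df$q <= 0) || is.unsorted(df$q, strictly = TRUE)) {
    abort("SAXS profile: q must be positive and strictly ascending")
  }
  as_tibble(df)
}

#' @rdname fp_io
#' @export
read_frap_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  .require_cols(df, c("t_s", "T1", "T2", "B"), "FRAP trace")
  tibble(t = df$t_s, T1 = df$T1, T2 = df$T2, B = df$B)
}

#' @rdname fp_io
#' @export
read_contour_traces <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .require_cols(df, c("fibril_id", "x_nm", "y_nm"), "contour traces")
  as_tibble(df)
}

#' @rdname fp_io
#' @export
read_phase_observations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .require_cols(df, c("pH", "c_wt_percent"), "phase observations")
  out <- tibble(pH = df$pH, c_mean = df$c_wt_percent)
  if ("c_min_wt_percent" %in% names(df)) out$c_min <- df$c_min_wt_percent
  if ("regime_label" %in% names(df)) out$regime_label <- df$regime_label
  out
}

#' @rdname fp_io
#' @param x Table to write.
#' @export
write_result_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
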