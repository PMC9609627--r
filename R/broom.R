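#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of an SLS relaxation fit
#'
#' @param x An `sls_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.sls_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric()))
  }
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm),
                 estimate = sm[, "Estimate"],
                 std.error = sm[, "Std. Error"])
}

#' One-row summary of an SLS relaxation fit
#'
#' @param x An `sls_fit`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `converged`, `degenerate`, `nobs`.
#' @export
glance.sls_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2,
                 converged = x$converged,
                 degenerate = isTRUE(x$degenerate),
                 nobs = if (x$converged) length(stats::resid(x$fit)) else NA_integer_)
}

#' Tidy a Lissajous analysis into per-signal rows
#'
#' @param x A `lissajous_result`.
#' @param ... Unused.
#' @return Tibble with one row per fitted signal (stress, strain):
#'   amplitude, phase, offset, frequency, rmse.
#' @export
tidy.lissajous_result <- function(x, ...) {
  row <- function(nm, f) tibble::tibble(
    signal = nm, amplitude = f$amplitude, phase_rad = f$phase_rad,
    offset = f$offset, freq_Hz = f$freq_Hz, rmse = f$rmse)
  dplyr::bind_rows(row("stress", x$stress_fit), row("strain", x$strain_fit))
}

#' One-row summary of a Lissajous analysis
#'
#' @param x A `lissajous_result`.
#' @param ... Unused.
#' @return Tibble with `E_c_kPa`, `loop_area_kPa`, `phase_lag_rad`,
#'   `L_x`, `L_y`.
#' @export
glance.lissajous_result <- function(x, ...) {
  tibble::tibble(E_c_kPa = x$E_c_kPa, loop_area_kPa = x$loop_area_kPa,
                 phase_lag_rad = x$phase_lag_rad, L_x = x$L_x, L_y = x$L_y)
}

#' Tidy the per-window slopes of a constant-force measurement
#'
#' @param x A `constant_force_result`.
#' @param ... Unused.
#' @return The `per_window` tibble (`n_samples`, `E_cf_kPa`).
#' @export
tidy.constant_force_result <- function(x, ...) x$per_window

#' One-row summary of a constant-force measurement
#'
#' @param x A `constant_force_result`.
#' @param ... Unused.
#' @return Tibble with `E_cf_kPa` and the window bounds.
#' @export
glance.constant_force_result <- function(x, ...) {
  tibble::tibble(E_cf_kPa = x$E_cf_kPa,
                 window_from = x$window[1], window_to = x$window[2])
}
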