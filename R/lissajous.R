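#' Microfiber cross-section specification
#'
#' @param diameter_um Fiber diameter in um (circular section assumed);
#'   ignored when `S_um2` is given directly.
#' @param L0_um Initial (gauge) length in um.
#' @param S_um2 Optional cross-section area in um^2.
#' @return An object of class `fiber_spec`.
#' @examples
#' fiber_spec(diameter_um = 150, L0_um = 1000)
#' @export
fiber_spec <- function(diameter_um = 150, L0_um = 1000, S_um2 = NULL) {
  if (is.null(S_um2)) S_um2 <- pi * diameter_um^2 / 4
  stopifnot(S_um2 > 0, L0_um > 0)
  structure(list(S_um2 = S_um2, L0_um = L0_um, diameter_um = diameter_um),
            class = "fiber_spec")
}

#' Tensile stress from stretching force
#'
#' sigma = F / S, converted from uN/um^2 (= MPa) to kPa.
#'
#' @param force_uN Force series in uN.
#' @param fiber A [fiber_spec()].
#' @return Stress in kPa.
#' @export
stress_series <- function(force_uN, fiber) {
  stopifnot(inherits(fiber, "fiber_spec"))
  force_uN / fiber$S_um2 * 1e3
}

#' Tensile strain from manipulator travel and tip deflection
#'
#' epsilon = (L_m - u_tip) / L0: the fiber elongation is the manipulator
#' displacement minus the sensing-tube tip deflection. Setting
#' `drop_u_tip = TRUE` uses the approximation epsilon = L_m / L0
#' (valid when the sensing tube is much stiffer than the fiber).
#'
#' @param L_m_um Manipulator displacement series in um.
#' @param u_tip_um Tip-deflection series in um (same length).
#' @param fiber A [fiber_spec()].
#' @param drop_u_tip Use the L_m-only approximation (default FALSE).
#' @return Dimensionless strain.
#' @export
strain_series <- function(L_m_um, u_tip_um, fiber, drop_u_tip = FALSE) {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (fiber$L0_um == 0) stop("L0 must be nonzero", call. = FALSE)
  if (length(L_m_um) != length(u_tip_um)) {
    stop("L_m_um and u_tip_um must have equal length", call. = FALSE)
  }
  if (drop_u_tip) L_m_um / fiber$L0_um else (L_m_um - u_tip_um) / fiber$L0_um
}

#' Fit a phase-shifted sinusoid to a signal
#'
#' y = A sin(2 pi f t + phase) + offset. With a known frequency the fit is
#' an exact linear least squares on a sin/cos basis; with `freq_Hz = NULL`
#' the frequency is seeded from the periodogram peak and refined by
#' Levenberg-Marquardt. A signal without detectable oscillation (flat, or
#' no spectral peak) yields `ok = FALSE` rather than a spurious fit.
#'
#' @param t_s Time stamps in s.
#' @param y Signal values.
#' @param freq_Hz Known frequency in Hz, or NULL to fit it.
#' @return An object of class `sinusoid_fit` with fields `amplitude`,
#'   `phase_rad` in (-pi, pi\], `offset`, `freq_Hz`, `rmse`, `ok`.
#' @export
fit_sinusoid <- function(t_s, y, freq_Hz = NULL) {
  stopifnot(length(t_s) == length(y), length(y) >= 8)
  fitted_freq <- is.null(freq_Hz)
  if (fitted_freq) {
    if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1e-300)) {
      return(new_sinusoid_fit(NA, NA, mean(y), NA, NA, ok = FALSE,
                              note = "constant signal: no frequency identifiable"))
    }
    sp <- stats::spec.pgram(stats::ts(y - mean(y), deltat = mean(diff(t_s))),
                            plot = FALSE, taper = 0, detrend = FALSE)
    freq_Hz <- sp$freq[which.max(sp$spec)]
  }
  w <- 2 * pi * freq_Hz
  X <- cbind(s = sin(w * t_s), c = cos(w * t_s))
  lf <- stats::lm(y ~ X)
  cf <- stats::coef(lf)
  a <- unname(cf["Xs"]); b <- unname(cf["Xc"]); c0 <- unname(cf["(Intercept)"])
  if (fitted_freq) {
    st <- list(A = sqrt(a^2 + b^2), phase = atan2(b, a), c0 = c0, f = freq_Hz)
    nl <- tryCatch(minpack.lm::nlsLM(
      y ~ A * sin(2 * pi * f * t_s + phase) + c0,
      data = data.frame(t_s = t_s, y = y),
      start = st, control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(nl)) {
      return(new_sinusoid_fit(NA, NA, NA, NA, NA, ok = FALSE,
                              note = "frequency refinement did not converge"))
    }
    cf <- stats::coef(nl)
    A <- unname(cf["A"]); ph <- unname(cf["phase"])
    c0 <- unname(cf["c0"]); freq_Hz <- unname(cf["f"])
    rmse <- sqrt(mean(stats::resid(nl)^2))
  } else {
    A <- sqrt(a^2 + b^2); ph <- atan2(b, a)
    rmse <- sqrt(mean(stats::resid(lf)^2))
  }
  if (A < 0) { A <- -A; ph <- ph + pi }
  ph <- ((ph + pi) %% (2 * pi)) - pi
  if (ph == -pi) ph <- pi
  new_sinusoid_fit(A, ph, c0, freq_Hz, rmse, ok = TRUE)
}

new_sinusoid_fit <- function(amplitude, phase_rad, offset, freq_Hz, rmse,
                             ok, note = NULL) {
  structure(list(amplitude = amplitude, phase_rad = phase_rad,
                 offset = offset, freq_Hz = freq_Hz, rmse = rmse,
                 ok = ok, note = note),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  if (!x$ok) {
    cat("<sinusoid_fit> FAILED:", x$note, "\n")
  } else {
    cat(sprintf(
      "<sinusoid_fit> A = %.6g, phase = %.4g rad, offset = %.6g, f = %g Hz (rmse %.3g)\n",
      x$amplitude, x$phase_rad, x$offset, x$freq_Hz, x$rmse))
  }
  invisible(x)
}

#' Elastic modulus and loop area from fitted stress/strain sinusoids
#'
#' Builds the elliptical Lissajous stress-strain loop from the two fits
#' and extracts: the cyclic elastic modulus E_c = sigma0 / epsilon0, the
#' long-axis projections L_x, L_y of the loop (computed geometrically from
#' the principal axis of the amplitude-normalised ellipse; the crossover
#' point of the long axis with the ellipse projects to
#' (epsilon0, sigma0) cos(lag/2), so L_y / L_x = sigma0 / epsilon0 and the
#' two routes agree to numerical precision), and the dissipated energy
#' density per cycle, area = pi sigma0 epsilon0 |sin(delta - phi)|.
#'
#' @param stress_fit [fit_sinusoid()] of the stress in kPa.
#' @param strain_fit [fit_sinusoid()] of the dimensionless strain.
#' @param freq_tol Relative frequency mismatch tolerance (default 1e-6).
#' @return An object of class `lissajous_result` with fields `E_c_kPa`,
#'   `L_x`, `L_y`, `loop_area_kPa`, `phase_lag_rad`, and the two fits.
#' @export
lissajous_modulus <- function(stress_fit, strain_fit, freq_tol = 1e-6) {
  stopifnot(inherits(stress_fit, "sinusoid_fit"),
            inherits(strain_fit, "sinusoid_fit"))
  if (!stress_fit$ok || !strain_fit$ok) {
    stop("both sinusoid fits must have succeeded", call. = FALSE)
  }
  if (abs(stress_fit$freq_Hz - strain_fit$freq_Hz) >
      freq_tol * strain_fit$freq_Hz) {
    stop("stress and strain fits are at different frequencies", call. = FALSE)
  }
  s0 <- stress_fit$amplitude
  e0 <- strain_fit$amplitude
  if (e0 <= 0) stop("zero strain amplitude", call. = FALSE)
  lag <- stress_fit$phase_rad - strain_fit$phase_rad
  lag <- ((lag + pi) %% (2 * pi)) - pi
  # geometric long-axis projections from the normalised parametric loop
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  xn <- sin(th); yn <- sin(th + lag)
  cv <- stats::cov(cbind(xn, yn)) * (length(th) - 1) / length(th)
  eg <- eigen(cv, symmetric = TRUE)
  axis_dir <- eg$vectors[, 1]
  half_len <- sqrt(2 * eg$values[1])
  L_x <- abs(axis_dir[1]) * half_len * e0
  L_y <- abs(axis_dir[2]) * half_len * s0
  area <- pi * s0 * e0 * abs(sin(lag))
  structure(list(E_c_kPa = s0 / e0, L_x = L_x, L_y = L_y,
                 loop_area_kPa = area, phase_lag_rad = lag,
                 stress_fit = stress_fit, strain_fit = strain_fit),
            class = "lissajous_result")
}

#' @export
print.lissajous_result <- function(x, ...) {
  cat(sprintf(
    "<lissajous_result> E_c = %.5g kPa, loop area = %.4g kPa, phase lag = %.4g rad\n",
    x$E_c_kPa, x$loop_area_kPa, x$phase_lag_rad))
  invisible(x)
}

#' Cyclic-loading modulus measurement from a closed-loop trace
#'
#' Converts a trace to stress and strain, fits both with phase-shifted
#' sinusoids at the command frequency (discarding the initial transient
#' cycles) and returns the Lissajous analysis.
#'
#' @param trace A `closed_loop_trace` (or any tibble with `t_s`,
#'   force and displacement columns).
#' @param fiber A [fiber_spec()].
#' @param freq_Hz Loading frequency; defaults to the trace's command
#'   attribute.
#' @param discard_cycles Transient cycles to drop before fitting
#'   (default 1).
#' @param use_measured Use the noisy measured force when available
#'   (default TRUE), else the true plant force.
#' @param drop_u_tip Passed to [strain_series()].
#' @return A `lissajous_result`.
#' @export
measure_modulus <- function(trace, fiber, freq_Hz = NULL, discard_cycles = 1,
                            use_measured = TRUE, drop_u_tip = FALSE) {
  cmd <- attr(trace, "command")
  if (is.null(freq_Hz)) {
    if (is.null(cmd)) stop("freq_Hz not given and trace has no command attribute",
                           call. = FALSE)
    freq_Hz <- cmd$frequency_Hz
  }
  force <- if (use_measured && "F_meas_uN" %in% names(trace))
    trace$F_meas_uN else trace$F_f_uN
  keep <- trace$t_s >= discard_cycles / freq_Hz
  if (sum(keep) < 16) stop("not enough samples after transient", call. = FALSE)
  t <- trace$t_s[keep]
  sigma <- stress_series(force[keep], fiber)
  eps <- strain_series(trace$L_m_um[keep], trace$u_tip_um[keep], fiber,
                       drop_u_tip = drop_u_tip)
  lissajous_modulus(fit_sinusoid(t, sigma, freq_Hz),
                    fit_sinusoid(t, eps, freq_Hz))
}

#' Analytic dynamic modulus of an SLS fiber
#'
#' |G(i omega)| L0 / S in kPa: the oracle value the cyclic measurement
#' should reproduce at the loading frequency.
#'
#' @param params An [sls_parameters()].
#' @param fiber A [fiber_spec()].
#' @param freq_Hz Frequency in Hz.
#' @return Modulus magnitude in kPa (vectorised over `freq_Hz`).
#' @export
sls_dynamic_modulus <- function(params, fiber, freq_Hz) {
  fr <- sls_frequency_response(params, freq_Hz)
  fr$magnitude * fiber$L0_um / fiber$S_um2 * 1e3
}

#' Loop-area ordering across loading frequencies
#'
#' Sorts Lissajous results by frequency and reports whether the dissipated
#' area per cycle is monotone non-decreasing. For an SLS fiber this
#' ordering holds below the corner frequency 1/(2 pi tau), where the loss
#' modulus still grows with omega; above it the model predicts the
#' reverse. Amplitudes must match across runs for areas to be comparable.
#'
#' @param results List of `lissajous_result`s at a common amplitude.
#' @param amp_tol Relative amplitude-consistency tolerance (default 5%).
#' @return Tibble with `freq_Hz`, `loop_area_kPa`, `E_c_kPa` sorted by
#'   frequency, plus attribute `monotone_nondecreasing`.
#' @export
loop_area_vs_frequency <- function(results, amp_tol = 0.05) {
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, logical(1), "lissajous_result")))
  s0 <- vapply(results, function(r) r$stress_fit$amplitude, numeric(1))
  e0 <- vapply(results, function(r) r$strain_fit$amplitude, numeric(1))
  consistent <- function(v) diff(range(v)) <= amp_tol * max(mean(v), 1e-300)
  if (!consistent(s0) && !consistent(e0)) {
    stop("results mix different loading amplitudes; areas are not comparable",
         call. = FALSE)
  }
  fr <- vapply(results, function(r) r$stress_fit$freq_Hz, numeric(1))
  out <- tibble::tibble(
    freq_Hz = fr,
    loop_area_kPa = vapply(results, function(r) r$loop_area_kPa, numeric(1)),
    E_c_kPa = vapply(results, function(r) r$E_c_kPa, numeric(1)))
  out <- out[order(out$freq_Hz), ]
  attr(out, "monotone_nondecreasing") <-
    !is.unsorted(out$loop_area_kPa, strictly = FALSE)
  out
}

#' Simulate a constant-velocity ramp loading
#'
#' Traditional constant-force-loading control experiment: the manipulating
#' tube moves at a fixed speed and the fiber force follows the SLS ramp
#' response F(t) = lambda1 v t + lambda2 v tau (1 - e^(-t/tau)), sampled
#' at the acquisition interval.
#'
#' @param params An [sls_parameters()].
#' @param speed_mm_min Elongation speed in mm/min (default 10).
#' @param t_end_s Ramp duration in s.
#' @param dt_sample_s Sampling interval in s (default 0.2).
#' @param noise A [noise_spec()] or NULL.
#' @param tube Optional tube stiffness for the u_tip column (default as in
#'   [run_closed_loop()]).
#' @param seed Optional seed.
#' @return Tibble with `t_s`, `L_m_um`, `u_tip_um`, `F_f_uN`, `F_meas_uN`.
#' @export
simulate_ramp_loading <- function(params, speed_mm_min = 10, t_end_s = 4,
                                  dt_sample_s = 0.2, noise = NULL,
                                  tube = NULL, seed = NULL) {
  stopifnot(inherits(params, "sls_parameters"))
  if (is.null(tube)) tube <- stiffness_from_geometry(tube_geometry(70, 60, 70e9, 1e-12))
  K_tube <- if (inherits(tube, "tube_stiffness")) tube$K_uN_per_um else tube
  if (!is.null(seed)) set.seed(seed)
  v <- speed_mm_min * 1e3 / 60          # um/s
  t <- seq(0, t_end_s, by = dt_sample_s)
  u <- v * t
  f <- params$lambda1 * v * t +
    params$lambda2 * v * params$tau * (1 - exp(-t / params$tau))
  fm <- if (is.null(noise)) f else f + noise$draw(length(t))
  u_tip <- fm / K_tube
  tibble::tibble(t_s = t, L_m_um = u + u_tip, u_tip_um = u_tip,
                 F_f_uN = f, F_meas_uN = fm)
}

#' Constant-force-loading modulus with window sensitivity
#'
#' Ordinary least-squares slope of stress against strain over the loading
#' ramp, together with the window-sensitivity sweep: the slope re-fitted
#' on the first 2, 3, ..., n samples. On a viscoelastic fiber the early
#' windows (still in the quasi-linear range) give steeper slopes than the
#' full record, which is how the ramp method under-reports the modulus of
#' soft fibers.
#'
#' @param trace Ramp trace with `t_s`, `L_m_um`, `u_tip_um` and a force
#'   column (`F_meas_uN` preferred, else `F_f_uN`).
#' @param fiber A [fiber_spec()].
#' @param window Optional index range (length-2) of samples to use for the
#'   headline E_cf; default the whole ramp.
#' @param drop_u_tip Passed to [strain_series()].
#' @return An object of class `constant_force_result` with `E_cf_kPa`,
#'   `window`, and tibble `per_window` (columns `n_samples`,
#'   `E_cf_kPa`).
#' @export
constant_force_modulus <- function(trace, fiber, window = NULL,
                                   drop_u_tip = FALSE) {
  force <- if ("F_meas_uN" %in% names(trace)) trace$F_meas_uN else trace$F_f_uN
  sigma <- stress_series(force, fiber)
  eps <- strain_series(trace$L_m_um, trace$u_tip_um, fiber,
                       drop_u_tip = drop_u_tip)
  n <- length(sigma)
  if (is.null(window)) window <- c(1L, n)
  idx <- seq(window[1], window[2])
  if (length(idx) < 2) stop("window must span at least 2 samples", call. = FALSE)
  slope <- function(i) {
    if (stats::var(eps[i]) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(sigma[i] ~ eps[i]))[2])
  }
  per_window <- tibble::tibble(
    n_samples = 2:n,
    E_cf_kPa = vapply(2:n, function(k) slope(seq_len(k)), numeric(1)))
  structure(list(E_cf_kPa = slope(idx), window = window,
                 per_window = per_window),
            class = "constant_force_result")
}

#' @export
print.constant_force_result <- function(x, ...) {
  cat(sprintf("<constant_force_result> E_cf = %.5g kPa (samples %d..%d)\n",
              x$E_cf_kPa, x$window[1], x$window[2]))
  invisible(x)
}
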