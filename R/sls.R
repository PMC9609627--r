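#' Standard-linear-solid parameters of a microfiber
#'
#' The fiber is modelled as a spring (stiffness K2) in parallel with a
#' Maxwell arm (spring K1 in series with dashpot eta). In the lumped form
#' used throughout the package the stress-relaxation response to a step
#' displacement u0 is
#' \deqn{F(t) = (\lambda_1 + \lambda_2 e^{-t/\tau}) u_0,}
#' with lambda1 = S K2 / L0, lambda2 = S K1 / L0 and tau = eta / K1 when the
#' raw material constants are supplied.
#'
#' @param lambda1,lambda2 Long-time and decaying stiffness in uN/um.
#' @param tau Relaxation time constant in s.
#' @param K1_kPa,K2_kPa,eta_kPa_s,S_um2,L0_um Optional raw constants; when
#'   all are given the lambda-form is derived from them and `lambda1`,
#'   `lambda2`, `tau` may be omitted.
#' @return An object of class `sls_parameters`.
#' @examples
#' sls_parameters(11.23, 0.7629, 44.94)
#' @export
sls_parameters <- function(lambda1 = NULL, lambda2 = NULL, tau = NULL,
                           K1_kPa = NULL, K2_kPa = NULL, eta_kPa_s = NULL,
                           S_um2 = NULL, L0_um = NULL) {
  raw <- list(K1_kPa = K1_kPa, K2_kPa = K2_kPa, eta_kPa_s = eta_kPa_s,
              S_um2 = S_um2, L0_um = L0_um)
  if (all(!vapply(raw, is.null, logical(1)))) {
    # kPa * um2 / um = 1e-3 uN/um
    lambda1 <- 1e-3 * S_um2 * K2_kPa / L0_um
    lambda2 <- 1e-3 * S_um2 * K1_kPa / L0_um
    tau <- eta_kPa_s / K1_kPa
  }
  vals <- c(lambda1 = lambda1, lambda2 = lambda2, tau = tau)
  if (length(vals) != 3 || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("lambda1, lambda2 and tau must all be finite and positive",
         call. = FALSE)
  }
  structure(c(list(lambda1 = unname(lambda1), lambda2 = unname(lambda2),
                   tau = unname(tau)), raw),
            class = "sls_parameters")
}

#' @export
print.sls_parameters <- function(x, ...) {
  cat(sprintf(
    "<sls_parameters> lambda1 = %g uN/um, lambda2 = %g uN/um, tau = %g s\n",
    x$lambda1, x$lambda2, x$tau))
  invisible(x)
}

#' Fitted GelMA microfiber presets
#'
#' Relaxation parameters for microfibers spun at two GelMA concentrations,
#' as obtained from stress-relaxation fits: 7% w/v (lambda1 = 11.23,
#' lambda2 = 0.7629, tau = 44.94) and 5.5% w/v (lambda1 = 30.72,
#' lambda2 = 3.584, tau = 56.20), lambdas in uN/um, tau in s.
#'
#' @param name One of `"gelma_7pct"`, `"gelma_5p5pct"`.
#' @return An [sls_parameters()] object.
#' @export
gelma_preset <- function(name = c("gelma_7pct", "gelma_5p5pct")) {
  name <- match.arg(name)
  switch(name,
         gelma_7pct  = sls_parameters(11.23, 0.7629, 44.94),
         gelma_5p5pct = sls_parameters(30.72, 3.584, 56.20))
}

#' Stress-relaxation force of the SLS model
#'
#' F(t) = (lambda1 + lambda2 exp(-t/tau)) u0 for a step displacement u0
#' applied at t = 0.
#'
#' @param t_s Times in s (vectorised, must be >= 0).
#' @param params An [sls_parameters()].
#' @param u0_um Step displacement in um.
#' @return Force in uN.
#' @export
relaxation_force <- function(t_s, params, u0_um) {
  stopifnot(inherits(params, "sls_parameters"))
  if (any(!is.finite(t_s)) || any(t_s < 0)) {
    stop("t_s must be finite and non-negative", call. = FALSE)
  }
  (params$lambda1 + params$lambda2 * exp(-t_s / params$tau)) * u0_um
}

#' Simulate a stress-relaxation experiment
#'
#' Evaluates the closed-form relaxation curve on a regular grid and adds
#' optional Gaussian measurement noise, producing the kind of record the
#' relaxation fit consumes.
#'
#' @param params An [sls_parameters()].
#' @param u0_um Step displacement in um.
#' @param t_end_s,dt_s Time span and sampling interval in s.
#' @param noise_sd Additive Gaussian noise sd in uN (0 = noiseless).
#' @param seed Optional seed.
#' @return Tibble with columns `t_s`, `force_uN`.
#' @export
simulate_relaxation <- function(params, u0_um = 9, t_end_s = 200, dt_s = 0.5,
                                noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, t_end_s, by = dt_s)
  f <- relaxation_force(t, params, u0_um)
  if (noise_sd > 0) f <- f + stats::rnorm(length(t), 0, noise_sd)
  tibble::tibble(t_s = t, force_uN = f)
}

#' Fit the SLS relaxation model to a force-time record
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' F(t) = (lambda1 + lambda2 exp(-t/tau)) u0. Starting values default to a
#' moment-based guess (tail level for lambda1, initial excess for lambda2,
#' 1/3 of the span for tau).
#'
#' @param data Data frame with columns `t_s` and `force_uN`.
#' @param u0_um Step displacement used in the experiment, in um.
#' @param start Optional named list/vector with `lambda1`, `lambda2`, `tau`.
#' @return An object of class `sls_fit`: the fitted [sls_parameters()], the
#'   R^2, convergence status and the underlying `nls` object. If the
#'   decaying branch is not identifiable (lambda2 ~ 0) the fit is flagged
#'   `degenerate` and `tau` should not be interpreted.
#' @export
fit_sls <- function(data, u0_um, start = NULL) {
  stopifnot(all(c("t_s", "force_uN") %in% names(data)))
  t <- data$t_s
  f <- data$force_uN
  if (length(t) < 10) stop("need at least 10 samples", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("t_s must be strictly increasing", call. = FALSE)
  }
  if (is.null(start)) {
    tail_lvl <- mean(f[t >= stats::quantile(t, 0.8)]) / u0_um
    head_lvl <- f[1] / u0_um
    start <- list(lambda1 = max(tail_lvl, 1e-8),
                  lambda2 = max(head_lvl - tail_lvl, 1e-3 * abs(head_lvl), 1e-8),
                  tau = diff(range(t)) / 3)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      force_uN ~ (lambda1 + lambda2 * exp(-t_s / tau)) * u0_um,
      data = data.frame(t_s = t, force_uN = f),
      start = start,
      lower = c(lambda1 = 0, lambda2 = 0, tau = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE, message = conditionMessage(fit),
                          params = NULL, r2 = NA_real_, degenerate = NA,
                          fit = NULL, u0_um = u0_um),
                     class = "sls_fit"))
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((f - mean(f))^2)
  degenerate <- unname(cf["lambda2"]) < 1e-4 * unname(cf["lambda1"])
  params <- if (degenerate) NULL else
    sls_parameters(unname(cf["lambda1"]), unname(cf["lambda2"]), unname(cf["tau"]))
  structure(list(converged = TRUE, message = NULL, params = params,
                 coef = as.list(cf), r2 = r2, degenerate = degenerate,
                 fit = fit, u0_um = u0_um),
            class = "sls_fit")
}

#' @export
print.sls_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sls_fit> NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<sls_fit> lambda1 = %.4g, lambda2 = %.4g uN/um, tau = %.4g s (R^2 = %.4f)%s\n",
    x$coef$lambda1, x$coef$lambda2, x$coef$tau, x$r2,
    if (isTRUE(x$degenerate)) "  [degenerate: lambda2 ~ 0, tau unidentifiable]" else ""))
  invisible(x)
}

#' Complex dynamic stiffness of the SLS model
#'
#' Frequency response G(i omega) of the displacement-to-force transfer
#' function: G(s) = lambda1 + lambda2 * s tau / (1 + s tau), i.e.
#' storage part lambda1 + lambda2 (wt)^2/(1+(wt)^2) and loss part
#' lambda2 wt/(1+(wt)^2).
#'
#' @param params An [sls_parameters()].
#' @param freq_Hz Frequencies in Hz (vectorised).
#' @return Tibble with columns `freq_Hz`, `G` (complex, uN/um),
#'   `magnitude`, `phase_rad`, `storage`, `loss`.
#' @export
sls_frequency_response <- function(params, freq_Hz) {
  stopifnot(inherits(params, "sls_parameters"))
  w <- 2 * pi * freq_Hz
  s <- 1i * w
  G <- params$lambda1 + params$lambda2 * s * params$tau / (1 + s * params$tau)
  tibble::tibble(freq_Hz = freq_Hz, G = G,
                 magnitude = Mod(G), phase_rad = Arg(G),
                 storage = Re(G), loss = Im(G))
}
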