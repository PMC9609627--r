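#' Augmented state-space realisation of the SLS plant
#'
#' Realises the displacement-to-force transfer function of the SLS model,
#' G(s) = ((lambda1+lambda2) s + lambda1/tau) / (s + 1/tau), as a one-state
#' system with pole -1/tau and feedthrough lambda1+lambda2, augmented with
#' the integral tracking state e_yI = integral of (F_f - F_cmd) dt:
#' \deqn{\dot x = A x + B (u + f) + B_{ref} F_{cmd}, \quad
#'       y = C x + D (u + f)}
#' with x = (e_yI, x_p), A = \[\[0, 1\], \[0, -1/tau\]\],
#' B = (lambda1+lambda2, -lambda2/tau), B_ref = (-1, 0), C = I and
#' D = (0, lambda1+lambda2). The second output row is the force F_f;
#' correctness is defined by reproducing the closed-form relaxation
#' response, which the test-suite asserts.
#'
#' @param params An [sls_parameters()].
#' @return An object of class `sls_state_space` with matrices `A`, `B`,
#'   `B_ref`, `C`, `D`, state labels and the originating parameters.
#' @export
to_state_space <- function(params) {
  stopifnot(inherits(params, "sls_parameters"))
  l1 <- params$lambda1; l2 <- params$lambda2; tau <- params$tau
  m <- list(
    A = matrix(c(0, 0, 1, -1 / tau), 2, 2),
    B = matrix(c(l1 + l2, -l2 / tau), 2, 1),
    B_ref = matrix(c(-1, 0), 2, 1),
    C = diag(2),
    D = matrix(c(0, l1 + l2), 2, 1),
    states = c("e_yI", "x_p"),
    params = params)
  structure(m, class = "sls_state_space")
}

#' @export
print.sls_state_space <- function(x, ...) {
  cat("<sls_state_space> states (e_yI, x_p); plant pole",
      format(x$A[2, 2]), "1/s; DC gain", format(x$params$lambda1),
      "uN/um; feedthrough", format(x$D[2, 1]), "uN/um\n")
  invisible(x)
}

#' Gaussian or uniform measurement-noise specification
#'
#' The vision-based force readout carries random noise characterised by its
#' mean absolute value. For a zero-mean Gaussian, E|n| = sigma sqrt(2/pi),
#' so sigma = mean_abs * sqrt(pi/2); for a zero-mean uniform on (-h, h),
#' E|n| = h/2, so h = 2 * mean_abs. A zero-mean model is used because a DC
#' disturbance would bias the force tracking, which is not observed.
#'
#' @param mean_abs_uN Mean absolute noise value in uN (default 0.277).
#' @param model `"gaussian"` (default) or `"uniform"`.
#' @return An object of class `noise_spec` with a `draw(n)` closure.
#' @export
noise_spec <- function(mean_abs_uN = 0.277, model = c("gaussian", "uniform")) {
  model <- match.arg(model)
  stopifnot(is.finite(mean_abs_uN), mean_abs_uN >= 0)
  draw <- if (model == "gaussian") {
    sigma <- mean_abs_uN * sqrt(pi / 2)
    function(n) stats::rnorm(n, 0, sigma)
  } else {
    h <- 2 * mean_abs_uN
    function(n) stats::runif(n, -h, h)
  }
  structure(list(mean_abs_uN = mean_abs_uN, model = model, draw = draw),
            class = "noise_spec")
}

#' Simulate the open-loop SLS plant under a prescribed displacement
#'
#' Fixed-step 4th-order Runge-Kutta integration of the plant state with a
#' user-supplied displacement signal u(t), plus additive measurement noise
#' on the force output. The step must resolve the relaxation time: dt above
#' tau/20 warns, above tau/5 is refused.
#'
#' @param model An [to_state_space()] realisation.
#' @param u_fun Function of time returning the displacement in um
#'   (vectorised not required).
#' @param t_end_s Simulation horizon in s.
#' @param dt_s Time step in s (default tau/100).
#' @param noise A [noise_spec()] or NULL for noiseless output.
#' @param seed Optional seed; the trace is deterministic given the seed.
#' @return Tibble with columns `t_s`, `u_um`, `force_uN` (noisy measured
#'   force) and `force_true_uN`.
#' @export
simulate_plant <- function(model, u_fun, t_end_s, dt_s = NULL,
                           noise = NULL, seed = NULL) {
  stopifnot(inherits(model, "sls_state_space"))
  tau <- model$params$tau
  if (is.null(dt_s)) dt_s <- tau / 100
  if (dt_s > tau / 5) {
    stop("dt_s exceeds tau/5; the relaxation dynamics would be unresolved",
         call. = FALSE)
  }
  if (dt_s > tau / 20) {
    warning("dt_s exceeds tau/20; integration accuracy may suffer")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(t_end_s / dt_s)
  t <- seq(0, by = dt_s, length.out = n + 1)
  a <- model$A[2, 2]    # -1/tau
  b <- model$B[2, 1]    # -lambda2/tau
  d <- model$D[2, 1]    # lambda1+lambda2
  xp <- numeric(n + 1)
  x <- 0
  for (k in seq_len(n)) {
    t0 <- t[k]
    u1 <- u_fun(t0); u2 <- u_fun(t0 + dt_s / 2); u4 <- u_fun(t0 + dt_s)
    k1 <- a * x + b * u1
    k2 <- a * (x + dt_s / 2 * k1) + b * u2
    k3 <- a * (x + dt_s / 2 * k2) + b * u2
    k4 <- a * (x + dt_s * k3) + b * u4
    x <- x + dt_s / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    xp[k + 1] <- x
  }
  u <- vapply(t, u_fun, numeric(1))
  f_true <- xp + d * u
  f_meas <- if (is.null(noise)) f_true else f_true + noise$draw(n + 1)
  tibble::tibble(t_s = t, u_um = u, force_uN = f_meas, force_true_uN = f_true)
}
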