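#' Re-run the package's reference simulation study
#'
#' Recomputes, from scratch, the quantities the simulator is built around:
#' closed-loop tracking error on both GelMA plants (design on 7%, also run
#' against 5.5% for robustness), the optics pixel scales, relaxation
#' parameter recovery, the state-space step-response residual against the
#' closed-form relaxation, and the cyclic modulus against the analytic SLS
#' dynamic modulus.
#'
#' @param seed Integer seed driving every stochastic component.
#' @param n_cycles Loading cycles for the tracking runs (default 3).
#' @return Tibble with columns `check`, `measured`, `bound`, `comparison`,
#'   `pass`.
#' @export
reproduce_report <- function(seed = 1, n_cycles = 3) {
  p7 <- gelma_preset("gelma_7pct")
  p55 <- gelma_preset("gelma_5p5pct")
  model <- to_state_space(p7)
  design <- controller_design(model)
  cmd <- loading_command(5, 5, 0.01, n_cycles = n_cycles)

  tr7 <- run_closed_loop(p7, design, cmd, noise_spec(), seed = seed)
  tr55 <- run_closed_loop(p55, design, cmd, noise_spec(), seed = seed + 1)
  e7 <- tracking_error(tr7)$max_err_uN
  e55 <- tracking_error(tr55)$max_err_uN

  px1 <- pixel_to_micron(1, optics_spec(objective_factor = 1))
  px2 <- pixel_to_micron(1, optics_spec(objective_factor = 4 * 0.5))

  rel <- simulate_relaxation(p7, u0_um = 9, t_end_s = 200, dt_s = 0.5)
  fit <- fit_sls(rel, u0_um = 9,
                 start = list(lambda1 = p7$lambda1 * 1.5,
                              lambda2 = p7$lambda2 * 1.5,
                              tau = p7$tau * 1.5))
  l1_err <- abs(fit$coef$lambda1 - p7$lambda1) / p7$lambda1

  step <- simulate_plant(model, function(t) 9, t_end_s = 200, dt_s = p7$tau / 100)
  step_err <- max(abs(step$force_true_uN[-1] -
                        relaxation_force(step$t_s[-1], p7, 9)))

  fiber <- fiber_spec()
  lis <- measure_modulus(tr7, fiber)
  E_ref <- sls_dynamic_modulus(p7, fiber, 0.01)
  ec_err <- abs(lis$E_c_kPa - E_ref) / E_ref

  tibble::tibble(
    check = c("tracking max err, 7% plant (uN)",
              "tracking max err, 5.5% plant / mismatched controller (uN)",
              "pixel scale, bare sensor (um/px)",
              "pixel scale, 4x0.5 objective (um/px)",
              "relaxation fit: relative lambda1 recovery error",
              "state-space step response vs closed form (uN)",
              "cyclic E_c vs analytic dynamic modulus (relative)"),
    measured = c(e7, e55, px1, px2, l1_err, step_err, ec_err),
    bound = c(1, 1, 4.4, 2.2, 1e-3, 1e-6, 0.02),
    comparison = c("<", "<", "==", "==", "<", "<", "<"),
    pass = c(e7 < 1, e55 < 1,
             isTRUE(all.equal(px1, 4.4)), isTRUE(all.equal(px2, 2.2)),
             l1_err < 1e-3, step_err < 1e-6, ec_err < 0.02))
}
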