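# Stress/strain construction, sinusoid fitting, Lissajous loops, modulus
# extraction and the constant-force ramp comparison.

test_that("stress and strain arithmetic is exact", {
  fiber <- fx_fiber()   # d = 150 um -> S = pi * 75^2
  expect_identical(stress_series(0, fiber), 0)
  # 5 uN over pi*5625 um^2 = 2.8294e-4 MPa = 0.28294 kPa (hand arithmetic)
  expect_equal(stress_series(5, fiber), 5 / (pi * 5625) * 1e3,
               tolerance = 1e-12)
  half <- fiber_spec(S_um2 = 2 * fiber$S_um2, L0_um = 1000)
  expect_equal(stress_series(5, half), stress_series(5, fiber) / 2)

  expect_equal(strain_series(110, 10, fiber), 0.1)
  expect_identical(strain_series(c(5, 7), c(5, 7), fiber), c(0, 0))
  expect_error(strain_series(1:3, 1:2, fiber), "equal length")
})

test_that("dropping u_tip biases strain by at most the deflection share", {
  fiber <- fx_fiber()
  tr <- fx_trace7()
  keep <- tr$t_s > 100
  full <- strain_series(tr$L_m_um[keep], tr$u_tip_um[keep], fiber)
  approx <- strain_series(tr$L_m_um[keep], tr$u_tip_um[keep], fiber,
                          drop_u_tip = TRUE)
  rel_err <- max(abs(approx - full)) / max(abs(approx))
  bound <- max(abs(tr$u_tip_um[keep])) / max(abs(tr$L_m_um[keep]))
  expect_lte(rel_err, bound + 1e-12)
  # the deviation is exactly the tip-deflection share of the travel
  expect_equal(max(abs(approx - full)),
               max(abs(tr$u_tip_um[keep])) / fiber$L0_um, tolerance = 1e-12)
})

test_that("sinusoid fitting is exact on clean signals and honest on flat ones", {
  t <- seq(0, 500, 2)
  y <- 5 * sin(2 * pi * 0.01 * t) + 5
  fit <- fit_sinusoid(t, y, freq_Hz = 0.01)
  expect_equal(fit$amplitude, 5, tolerance = 1e-9)
  expect_equal(fit$offset, 5, tolerance = 1e-9)
  expect_equal(fit$phase_rad, 0, tolerance = 1e-9)
  # free-frequency route recovers the same signal
  fit_free <- fit_sinusoid(t, y)
  expect_true(fit_free$ok)
  expect_equal(fit_free$freq_Hz, 0.01, tolerance = 1e-6)
  # flat signal with free frequency: explicit failure
  flat <- fit_sinusoid(t, rep(3, length(t)))
  expect_false(flat$ok)
})

test_that("amplitude recovery stays within 2% under additive noise", {
  t <- seq(0, 500, 2)
  amps <- vapply(1:100, function(s) {
    set.seed(s)
    y <- 5 * sin(2 * pi * 0.01 * t) + 5 + rnorm(length(t), 0, 0.2)
    fit_sinusoid(t, y, freq_Hz = 0.01)$amplitude
  }, numeric(1))
  expect_equal(mean(amps), 5, tolerance = 0.02)
})

test_that("the Lissajous construction is geometrically consistent", {
  sfit <- fit_sinusoid(seq(0, 400, 1),
                       2 * sin(2 * pi * 0.01 * seq(0, 400, 1) + 0.3) + 4,
                       freq_Hz = 0.01)
  efit <- fit_sinusoid(seq(0, 400, 1),
                       0.05 * sin(2 * pi * 0.01 * seq(0, 400, 1) + 0.1) + 0.1,
                       freq_Hz = 0.01)
  res <- lissajous_modulus(sfit, efit)
  # the long-axis projection ratio equals the amplitude ratio
  expect_equal(res$L_y / res$L_x, res$E_c_kPa, tolerance = 1e-6)
  expect_equal(res$E_c_kPa, 2 / 0.05, tolerance = 1e-9)
  # loop area formula against numerically integrated contour area
  th <- seq(0, 2 * pi, length.out = 20001)
  x <- 0.05 * sin(th); y <- 2 * sin(th + res$phase_lag_rad)
  shoelace <- abs(sum(x[-1] * diff(y) - y[-1] * diff(x))) / 2
  expect_equal(res$loop_area_kPa, shoelace, tolerance = 1e-3)

  # no phase lag: degenerate line, zero area
  efit0 <- fit_sinusoid(seq(0, 400, 1),
                        0.05 * sin(2 * pi * 0.01 * seq(0, 400, 1) + 0.3) + 0.1,
                        freq_Hz = 0.01)
  res0 <- lissajous_modulus(sfit, efit0)
  expect_equal(res0$loop_area_kPa, 0, tolerance = 1e-9)
  expect_equal(res0$E_c_kPa, 40, tolerance = 1e-9)
  # mismatched frequencies are refused
  efit_wrong <- fit_sinusoid(seq(0, 400, 1),
                             0.05 * sin(2 * pi * 0.02 * seq(0, 400, 1)),
                             freq_Hz = 0.02)
  expect_error(lissajous_modulus(sfit, efit_wrong), "different frequencies")
})

test_that("cyclic modulus matches the analytic SLS dynamic modulus", {
  fiber <- fx_fiber()
  res <- measure_modulus(fx_trace7(), fiber)
  E_ref <- sls_dynamic_modulus(fx_params7(), fiber, 0.01)
  expect_equal(res$E_c_kPa, E_ref, tolerance = 0.02)
  g <- glance(res)
  expect_named(g, c("E_c_kPa", "loop_area_kPa", "phase_lag_rad", "L_x", "L_y"))
})

test_that("measured modulus is invariant to command amplitude", {
  fiber <- fx_fiber()
  Es <- vapply(fx_amp_sweep(), function(tr)
    measure_modulus(tr, fiber)$E_c_kPa, numeric(1))
  # 4 vs 6 uN agree within 3%, full sweep CV well under 5%
  expect_lt(abs(Es[2] - Es[4]) / Es[4], 0.03)
  expect_lt(sd(Es) / mean(Es), 0.05)
})

test_that("loop area grows with frequency below the SLS corner frequency", {
  p <- fx_params7()
  m <- to_state_space(p)
  fiber <- fx_fiber()
  freqs <- c(5e-4, 1e-3, 2e-3)    # corner 1/(2 pi tau) = 3.5e-3 Hz
  results <- lapply(freqs, function(f) {
    sim <- simulate_plant(m, function(t) 0.5 * sin(2 * pi * f * t) + 0.5,
                          t_end_s = 3 / f)
    keep <- sim$t_s >= 1 / f
    sfit <- fit_sinusoid(sim$t_s[keep],
                         stress_series(sim$force_true_uN[keep], fiber), f)
    efit <- fit_sinusoid(sim$t_s[keep], sim$u_um[keep] / fiber$L0_um, f)
    lissajous_modulus(sfit, efit)
  })
  rep <- loop_area_vs_frequency(results)
  expect_true(attr(rep, "monotone_nondecreasing"))
  expect_true(all(diff(rep$loop_area_kPa) > 0))
  # duplicated frequency: equal areas
  rep2 <- loop_area_vs_frequency(results[c(1, 1)])
  expect_equal(diff(rep2$loop_area_kPa), 0)
  # an almost purely elastic fiber dissipates almost nothing
  p_el <- sls_parameters(p$lambda1, 1e-8, p$tau)
  m_el <- to_state_space(p_el)
  sim <- simulate_plant(m_el, function(t) 0.5 * sin(2 * pi * 1e-3 * t) + 0.5,
                        t_end_s = 3000)
  keep <- sim$t_s >= 1000
  r_el <- lissajous_modulus(
    fit_sinusoid(sim$t_s[keep], stress_series(sim$force_true_uN[keep], fiber), 1e-3),
    fit_sinusoid(sim$t_s[keep], sim$u_um[keep] / fiber$L0_um, 1e-3))
  expect_lt(r_el$loop_area_kPa, 1e-6 * r_el$E_c_kPa)
  # mixed amplitudes are not comparable
  sim_big <- simulate_plant(m, function(t) 1.5 * sin(2 * pi * 1e-3 * t) + 1.5,
                            t_end_s = 3000)
  keep <- sim_big$t_s >= 1000
  r_big <- lissajous_modulus(
    fit_sinusoid(sim_big$t_s[keep],
                 stress_series(sim_big$force_true_uN[keep], fiber), 1e-3),
    fit_sinusoid(sim_big$t_s[keep], sim_big$u_um[keep] / fiber$L0_um, 1e-3))
  expect_error(loop_area_vs_frequency(list(results[[1]], r_big)), "amplitudes")
})

test_that("constant-force ramp: linear data is exact, SLS shows window sensitivity", {
  fiber <- fx_fiber()
  # perfectly linear synthetic stress-strain: slope E exactly, all windows
  E_true <- 500  # kPa
  u <- seq(0, 100, 5)
  lin <- tibble::tibble(t_s = seq_along(u) * 0.2, L_m_um = u,
                        u_tip_um = 0 * u,
                        F_f_uN = E_true * 1e-3 * fiber$S_um2 * u / fiber$L0_um)
  res_lin <- constant_force_modulus(lin, fiber)
  expect_equal(res_lin$E_cf_kPa, E_true, tolerance = 1e-9)
  expect_true(all(abs(res_lin$per_window$E_cf_kPa - E_true) < 1e-6))

  # SLS ramp relaxes underway: early-window slope exceeds the full-window
  # slope (the ordering that makes ramp fits under-read soft fibers)
  ramp <- simulate_ramp_loading(fx_params7(), t_end_s = 20)
  res <- constant_force_modulus(ramp, fiber)
  pw <- tidy(res)
  expect_gt(pw$E_cf_kPa[pw$n_samples == 2], res$E_cf_kPa)
  expect_gt(pw$E_cf_kPa[pw$n_samples == 3], res$E_cf_kPa)
  expect_error(constant_force_modulus(ramp, fiber, window = c(1, 1)),
               "at least 2")
})

test_that("ramp and cyclic measurements agree on the same fiber", {
  fiber <- fx_fiber()
  E_c <- measure_modulus(fx_trace7(), fiber)$E_c_kPa
  ramp <- simulate_ramp_loading(fx_params7(), t_end_s = 4)
  E_cf <- constant_force_modulus(ramp, fiber)$E_cf_kPa
  expect_lt(abs(E_cf - E_c) / E_c, 0.05)
})
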