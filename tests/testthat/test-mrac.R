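# Observer and LQR design, reference model, adaptive law, and the closed
# force-control loop.

test_that("observer placement achieves requested poles and degenerates gracefully", {
  m <- fx_model7()
  L <- design_observer(m, c(-1, -1.5))
  got <- sort(Re(eigen(m$A - L %*% m$C)$values))
  expect_equal(got, c(-1.5, -1), tolerance = 1e-8)
  # requesting the plant's own eigenvalues needs no correction
  L0 <- design_observer(m, eigen(m$A)$values)
  expect_lt(max(abs(L0)), 1e-10)
  # unobservable pair is refused with a named mode
  bad <- list(A = matrix(c(0, 0, 0, -1), 2, 2), C = matrix(c(0, 1), 1, 2))
  expect_error(design_observer(bad, c(-1, -2)), "unobservable")
})

test_that("LQR gain solves the Riccati equation and responds to weighting", {
  for (preset in c("gelma_7pct", "gelma_5p5pct")) {
    m <- to_state_space(gelma_preset(preset))
    lqr <- design_lqr(m, Q = diag(c(10, 1)), R = 1)
    res <- t(m$A) %*% lqr$P + lqr$P %*% m$A -
      lqr$P %*% m$B %*% t(m$B) %*% lqr$P / 1 + diag(c(10, 1))
    expect_lt(max(abs(res)), 1e-8)
    expect_true(all(Re(lqr$closed_loop_eig) < 0))
    # costlier input shrinks the gain
    lqr_cheap <- design_lqr(m, Q = diag(c(10, 1)), R = 100)
    expect_lt(sqrt(sum(lqr_cheap$Kx^2)), sqrt(sum(lqr$Kx^2)))
  }
  m <- fx_model7()
  expect_error(design_lqr(m, Q = diag(c(-1, 1)), R = 1), "positive definite")
  expect_error(design_lqr(m, Q = diag(2), R = 0), "positive scalar")
})

test_that("reference model carries certified Lyapunov solutions", {
  m <- fx_model7()
  d <- fx_design7()
  # P_ref certifies A_ref, P_err certifies A - L C; residuals at solver
  # precision, both symmetric positive definite
  for (pair in list(list(P = d$P_ref, A = d$A_ref),
                    list(P = d$P_err, A = m$A - d$L_obs %*% m$C))) {
    resid <- t(pair$A) %*% pair$P + pair$P %*% pair$A + d$Q_ref
    expect_lt(max(abs(resid)), 1e-9)
    expect_equal(pair$P, t(pair$P))
    expect_true(all(eigen(pair$P, symmetric = TRUE)$values > 0))
  }
  # independent elementwise check of the 2x2 Lyapunov identity for P_ref
  A <- d$A_ref; P <- d$P_ref
  expect_equal(2 * (A[1, 1] * P[1, 1] + A[2, 1] * P[1, 2]),
               -d$Q_ref[1, 1], tolerance = 1e-9)
  # zero gains collapse the reference model onto the plant (marginal:
  # the integrator eigenvalue sits at zero, so no certificate exists)
  expect_warning(ref0 <- build_reference_model(m, matrix(0, 2, 2), c(0, 0)),
                 "marginally stable")
  expect_equal(ref0$A_ref, m$A)
  expect_equal(ref0$C_ref, m$C)
  expect_null(ref0$P_ref)
})

test_that("adaptive update is a pure Lyapunov gradient step", {
  d <- fx_design7()
  st <- list(Theta_hat = rep(0.3, 1 + 2 * d$basis_order), x_ro = c(0.2, -0.1))
  # no error, no adaptation
  st2 <- adaptive_step(st, c(0, 0), d, dt_s = 0.1)
  expect_identical(st2$Theta_hat, st$Theta_hat)
  # gamma = 0 freezes the coefficients whatever the error
  d0 <- controller_design(fx_model7(), gamma = 0)
  st3 <- adaptive_step(st, c(1, 2), d0, dt_s = 0.1)
  expect_identical(st3$Theta_hat, st$Theta_hat)
  # the step moves along -gamma * phi * (e_x' P_err B_LD)
  ex <- c(0.5, -0.2)
  st4 <- adaptive_step(st, ex, d, dt_s = 0.1)
  drive <- as.numeric(t(ex) %*% d$P_err %*% d$B_LD)
  phi <- chebyshev_basis(st$x_ro, d$basis_order)
  expect_equal(st4$Theta_hat - st$Theta_hat, -0.1 * d$gamma * phi * drive)
  expect_error(adaptive_step(st, c(NA, 0), d, 0.1), "non-finite")
})

test_that("closed loop tracks the cyclic command within 1 uN on both plants", {
  err7 <- tracking_error(fx_trace7())
  err55 <- tracking_error(fx_trace55())
  expect_lt(err7$max_err_uN, 1)
  expect_lt(err55$max_err_uN, 1)   # controller designed on the 7% model
})

test_that("zero command and zero noise give an identically zero trace", {
  d <- fx_design7()
  tr <- run_closed_loop(fx_params7(), d,
                        loading_command(0, 0, 0.01, n_cycles = 1),
                        noise = NULL, seed = 1)
  expect_true(all(tr$F_f_uN == 0))
  expect_true(all(tr$L_m_um == 0))
  expect_true(all(tr$u_ad == 0))
})

test_that("equal seeds reproduce bit-identical traces", {
  d <- fx_design7()
  cmd <- loading_command(n_cycles = 1)
  a <- run_closed_loop(fx_params55(), d, cmd, noise_spec(), seed = 99)
  b <- run_closed_loop(fx_params55(), d, cmd, noise_spec(), seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("vanishing adaptation rate reduces to the pure LQR baseline", {
  d0 <- controller_design(fx_model7(), gamma = 0)
  cmd <- loading_command(n_cycles = 1)
  with_ad <- run_closed_loop(fx_params7(), d0, cmd, noise_spec(), seed = 5)
  without <- run_closed_loop(fx_params7(), d0, cmd, noise_spec(), seed = 5,
                             adapt = FALSE)
  expect_equal(with_ad$F_f_uN, without$F_f_uN, tolerance = 1e-12)
  expect_true(all(with_ad$u_ad == 0))
})

test_that("bounded command and noise keep force, displacement and coefficients bounded", {
  d <- fx_design7()
  tr <- run_closed_loop(fx_params55(), d, loading_command(n_cycles = 20),
                        noise_spec(), seed = 3)
  expect_true(all(is.finite(tr$F_f_uN)))
  expect_lt(max(abs(tr$F_f_uN)), 50)
  expect_lt(max(abs(tr$L_m_um)), 100)
  expect_true(all(is.finite(attr(tr, "Theta_hat"))))
  expect_lt(max(abs(attr(tr, "Theta_hat"))), 10)
  fs_cache$trace55_long <- tr   # reused by the adaptation-benefit check
})

test_that("adaptation does not worsen steady-state tracking on a mismatched plant", {
  d <- fx_design7()
  tr_ad <- fs_cache$trace55_long
  if (is.null(tr_ad)) {
    tr_ad <- run_closed_loop(fx_params55(), d, loading_command(n_cycles = 20),
                             noise_spec(), seed = 3)
  }
  tr_bl <- run_closed_loop(fx_params55(), d, loading_command(n_cycles = 20),
                           noise_spec(), seed = 3, adapt = FALSE)
  ss <- function(tr) {
    keep <- tr$t_s > 200
    sqrt(mean((tr$F_f_uN - tr$F_cmd_uN)[keep]^2))
  }
  expect_lte(ss(tr_ad), ss(tr_bl))
})

test_that("the Lyapunov candidate decreases along matched constant-uncertainty runs", {
  d <- fx_design7()
  ld <- lyapunov_diagnostic(d, f_const = 0.5,
                            command = loading_command(n_cycles = 2))
  dV <- diff(ld$V)
  expect_lte(max(dV), 1e-8 * max(abs(ld$V)))
})

test_that("a runaway adaptation rate is detected as instability", {
  d_bad <- controller_design(fx_model7(), gamma = 1e6)
  expect_error(
    run_closed_loop(fx_params7(), d_bad, loading_command(n_cycles = 1),
                    noise_spec(), seed = 1),
    class = "fiberstretch_unstable")
})

test_that("traces round-trip through the CSV interface", {
  tr <- fx_trace7()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, csv)
  back <- read_trace_csv(csv)
  expect_equal(back$F_f_uN, tr$F_f_uN, tolerance = 1e-12)
  expect_s3_class(back, "closed_loop_trace")
  # missing columns are reported by name
  broken <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tr[c("t_s", "F_cmd_uN")], broken)
  expect_error(read_trace_csv(broken), "L_m_um")
})
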