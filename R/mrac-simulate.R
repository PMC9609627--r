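#' Sinusoidal cyclic-loading force command
#'
#' F_cmd(t) = offset + amplitude * sin(2 pi f t). The offset must be at
#' least the amplitude so the commanded force never goes negative: the
#' fiber is only ever pulled, never pushed.
#'
#' @param offset_uN,amplitude_uN Offset and amplitude in uN.
#' @param frequency_Hz Loading frequency in Hz.
#' @param n_cycles Number of cycles to simulate.
#' @param dt_s Optional integration step override in s.
#' @return An object of class `loading_command` (callable as a function of
#'   time via `$f`).
#' @export
loading_command <- function(offset_uN = 5, amplitude_uN = 5,
                            frequency_Hz = 0.01, n_cycles = 3, dt_s = NULL) {
  if (!(offset_uN >= amplitude_uN && amplitude_uN >= 0)) {
    stop("need offset_uN >= amplitude_uN >= 0 (command must stay non-negative)",
         call. = FALSE)
  }
  if (frequency_Hz <= 0) stop("frequency_Hz must be positive", call. = FALSE)
  w <- 2 * pi * frequency_Hz
  structure(list(offset_uN = offset_uN, amplitude_uN = amplitude_uN,
                 frequency_Hz = frequency_Hz, n_cycles = n_cycles,
                 dt_s = dt_s,
                 f = function(t) amplitude_uN * sin(w * t) + offset_uN),
            class = "loading_command")
}

#' Chebyshev regressor for the adaptive law
#'
#' First-kind Chebyshev polynomials of each (normalised) observer state up
#' to `order`, sharing a single constant term:
#' Phi = (1, T1(z1)..Tk(z1), T1(z2)..Tk(z2)).
#'
#' @param z Normalised state vector (components in \[-1, 1\]).
#' @param order Maximum polynomial order (>= 1).
#' @return Numeric vector of length 1 + order * length(z).
#' @export
chebyshev_basis <- function(z, order = 3) {
  out <- 1
  for (zi in z) {
    Tk <- numeric(order)
    Tk[1] <- zi
    if (order >= 2) Tk[2] <- 2 * zi^2 - 1
    if (order >= 3) {
      for (k in 3:order) Tk[k] <- 2 * zi * Tk[k - 1] - Tk[k - 2]
    }
    out <- c(out, Tk)
  }
  out
}

#' One explicit-Euler update of the adaptive coefficients
#'
#' Theta_hat <- Theta_hat - dt * gamma * Phi * (e_x' P_err B_LD), the
#' Lyapunov-derived gradient law for the observer-state-feedback
#' architecture (the sign makes the Lyapunov function decrease; see the
#' methods vignette). With e_x = 0 or gamma = 0 the coefficients are
#' unchanged and the controller reduces to the pure LQR baseline.
#'
#' @param state List with `Theta_hat` and normalised regressor input
#'   `z_ro` (or raw `x_ro` treated as already normalised).
#' @param e_x State error x_bar - x_ro (length 2, finite).
#' @param design A [controller_design()].
#' @param dt_s Time step in s (> 0).
#' @return The updated state (same shape).
#' @export
adaptive_step <- function(state, e_x, design, dt_s) {
  stopifnot(inherits(design, "controller_design"), dt_s > 0)
  if (any(!is.finite(e_x))) {
    stop("non-finite state error e_x; adaptation aborted", call. = FALSE)
  }
  z <- if (!is.null(state$z_ro)) state$z_ro else state$x_ro
  phi <- chebyshev_basis(z, design$basis_order)
  drive <- as.numeric(t(e_x) %*% design$P_err %*% design$B_LD)
  state$Theta_hat <- state$Theta_hat - dt_s * design$gamma * phi * drive
  state
}

# shared integration-step rule: resolve plant relaxation, the command
# period and the fastest reference-model eigenvalue (explicit RK4 limit)
closed_loop_dt <- function(plant_tau, period, A_ref) {
  lam <- max(abs(Re(eigen(A_ref)$values)))
  min(plant_tau / 100, period / 200, 0.5 / lam)
}

#' Simulate the closed force-control loop
#'
#' Integrates plant, observer/reference model and adaptive law together
#' with fixed-step RK4. The plant may differ from the design model (the
#' robustness scenario); the adaptive law then absorbs the mismatch. The
#' measured force is the true plant force plus vision noise, and the
#' controller only ever sees measured quantities: the state error driving
#' adaptation uses x_bar = (e_yI, F_meas - D u), the model-frame state
#' reconstructed from the measurement.
#'
#' @param plant An [sls_parameters()] describing the true fiber.
#' @param design A [controller_design()] (possibly built on another model).
#' @param command A [loading_command()].
#' @param noise A [noise_spec()] or NULL.
#' @param seed Integer seed; traces are bit-identical for equal seeds.
#' @param adapt Logical: include the adaptive augmentation (default TRUE);
#'   FALSE freezes u_ad at 0 (pure baseline).
#' @param tube Optional `tube_stiffness` (or K in uN/um) used to convert
#'   measured force to the vision-side tip deflection; default is the K of
#'   a 70 mm glass tube glued at 60 mm (about 0.78 uN/um).
#' @param f_const Constant matched input disturbance in um added to the
#'   plant input (diagnostics; default 0).
#' @return A `closed_loop_trace`: tibble with columns `t_s`, `F_cmd_uN`,
#'   `F_f_uN` (true force), `F_meas_uN`, `L_m_um`, `u_tip_um`, `u_bl`,
#'   `u_ad`, `e_x1`, `e_x2`, and attributes `design`, `plant`, `dt_s`,
#'   `Theta_hat` (final coefficients).
#' @export
run_closed_loop <- function(plant, design, command = loading_command(),
                            noise = noise_spec(), seed = 1, adapt = TRUE,
                            tube = NULL, f_const = 0) {
  stopifnot(inherits(plant, "sls_parameters"),
            inherits(design, "controller_design"),
            inherits(command, "loading_command"))
  if (is.null(tube)) tube <- stiffness_from_geometry(tube_geometry(70, 60, 70e9, 1e-12))
  K_tube <- if (inherits(tube, "tube_stiffness")) tube$K_uN_per_um else tube
  set.seed(as.integer(seed))

  period <- 1 / command$frequency_Hz
  dt <- if (!is.null(command$dt_s)) command$dt_s else
    closed_loop_dt(plant$tau, period, design$A_ref)
  nstep <- ceiling(command$n_cycles * period / dt)
  cmd <- command$f

  # plant scalars (plant realisation frame)
  ap <- -1 / plant$tau
  bp <- -plant$lambda2 / plant$tau
  dp <- plant$lambda1 + plant$lambda2
  # design-model scalars
  Dm <- design$model$D[2, 1]
  Kx1 <- design$Kx[1, 1]; Kx2 <- design$Kx[1, 2]
  Aref <- design$A_ref
  L1 <- design$L_obs[1, ]; L2 <- design$L_obs[2, ]
  gPB <- design$gamma * as.numeric(design$P_err %*% design$B_LD)  # length 2
  nb <- 1 + 2 * design$basis_order
  ord <- design$basis_order

  draw <- if (is.null(noise)) function(n) numeric(n) else noise$draw
  noise_seq <- draw(nstep + 1)

  xp <- 0; eyI <- 0; xro1 <- 0; xro2 <- 0
  Th <- numeric(nb)
  zmin <- c(-1e-6, -1e-6); zmax <- c(1e-6, 1e-6)
  lim <- 100 * (command$offset_uN + command$amplitude_uN + 1e-9)

  n_out <- nstep + 1
  o_t <- numeric(n_out); o_cmd <- numeric(n_out); o_ff <- numeric(n_out)
  o_fm <- numeric(n_out); o_u <- numeric(n_out)
  o_ubl <- numeric(n_out); o_uad <- numeric(n_out)
  o_ex1 <- numeric(n_out); o_ex2 <- numeric(n_out)

  for (k in 0:nstep) {
    t0 <- k * dt
    nk <- noise_seq[k + 1]
    # normalisation bounds frozen within the step
    zmin <- pmin(zmin, c(xro1, xro2)); zmax <- pmax(zmax, c(xro1, xro2))
    zs <- 2 / (zmax - zmin); z0 <- zmin

    deriv <- function(s, tt) {
      xp_ <- s[1]; eyI_ <- s[2]; x1 <- s[3]; x2 <- s[4]
      z1 <- min(1, max(-1, zs[1] * (x1 - z0[1]) - 1))
      z2 <- min(1, max(-1, zs[2] * (x2 - z0[2]) - 1))
      phi <- chebyshev_basis(c(z1, z2), ord)
      uad <- if (adapt) sum(s[5:(4 + nb)] * phi) else 0
      u <- -(Kx1 * x1 + Kx2 * x2) + uad
      ff <- xp_ + dp * (u + f_const)
      fm <- ff + nk
      # state error from measurement-reconstructed model-frame state
      ex1 <- eyI_ - x1              # e_yI is itself a measured output
      ex2 <- (fm - Dm * u) - x2
      dxp <- ap * xp_ + bp * (u + f_const)
      deyI <- fm - cmd(tt)
      y1 <- eyI_; y2 <- fm
      dx1 <- Aref[1, 1] * x1 + Aref[1, 2] * x2 - cmd(tt) +
        L1[1] * y1 + L1[2] * y2
      dx2 <- Aref[2, 1] * x1 + Aref[2, 2] * x2 + L2[1] * y1 + L2[2] * y2
      dTh <- if (adapt) -(gPB[1] * ex1 + gPB[2] * ex2) * phi else numeric(nb)
      list(d = c(dxp, deyI, dx1, dx2, dTh),
           u = u, uad = uad, ff = ff, fm = fm, ex = c(ex1, ex2))
    }

    s <- c(xp, eyI, xro1, xro2, Th)
    d1 <- deriv(s, t0)
    if (!all(is.finite(d1$d))) {
      stop(sprintf("non-finite state at t = %.3f s; simulation aborted", t0),
           call. = FALSE)
    }
    if (abs(d1$ff) > lim) {
      cond <- structure(
        class = c("fiberstretch_unstable", "error", "condition"),
        list(message = sprintf(
          "closed loop unstable: |F_f| = %.3g uN exceeds 100x command at t = %.3f s",
          abs(d1$ff), t0), call = NULL))
      stop(cond)
    }
    ub <- -(Kx1 * xro1 + Kx2 * xro2)
    o_t[k + 1] <- t0; o_cmd[k + 1] <- cmd(t0)
    o_ff[k + 1] <- d1$ff; o_fm[k + 1] <- d1$fm
    o_u[k + 1] <- d1$u; o_ubl[k + 1] <- ub; o_uad[k + 1] <- d1$uad
    o_ex1[k + 1] <- d1$ex[1]; o_ex2[k + 1] <- d1$ex[2]

    d2 <- deriv(s + dt / 2 * d1$d, t0 + dt / 2)
    d3 <- deriv(s + dt / 2 * d2$d, t0 + dt / 2)
    d4 <- deriv(s + dt * d3$d, t0 + dt)
    s <- s + dt / 6 * (d1$d + 2 * d2$d + 2 * d3$d + d4$d)
    xp <- s[1]; eyI <- s[2]; xro1 <- s[3]; xro2 <- s[4]
    Th <- s[5:(4 + nb)]
  }

  u_tip <- o_fm / K_tube
  out <- tibble::tibble(
    t_s = o_t, F_cmd_uN = o_cmd, F_f_uN = o_ff, F_meas_uN = o_fm,
    L_m_um = o_u + u_tip, u_tip_um = u_tip,
    u_bl = o_ubl, u_ad = o_uad, e_x1 = o_ex1, e_x2 = o_ex2)
  attr(out, "design") <- design
  attr(out, "plant") <- plant
  attr(out, "dt_s") <- dt
  attr(out, "Theta_hat") <- Th
  attr(out, "K_tube") <- K_tube
  attr(out, "command") <- command[c("offset_uN", "amplitude_uN",
                                    "frequency_Hz", "n_cycles")]
  class(out) <- c("closed_loop_trace", class(out))
  out
}

#' Tracking-error summary of a closed-loop trace
#'
#' Maximum and RMS of |F_f - F_cmd| (true plant force against the command)
#' after an initial settling window, by default the first half loading
#' cycle.
#'
#' @param trace A `closed_loop_trace`.
#' @param after_s Settling time to discard; default half a command period.
#' @return Tibble with `max_err_uN`, `rms_err_uN`, `n`.
#' @export
tracking_error <- function(trace, after_s = NULL) {
  cmd <- attr(trace, "command")
  if (is.null(after_s)) {
    after_s <- if (!is.null(cmd)) 0.5 / cmd$frequency_Hz else
      0.1 * max(trace$t_s)
  }
  keep <- trace$t_s > after_s
  err <- abs(trace$F_f_uN - trace$F_cmd_uN)[keep]
  tibble::tibble(max_err_uN = max(err),
                 rms_err_uN = sqrt(mean(err^2)),
                 n = sum(keep))
}

#' Lyapunov-decrease diagnostic on a matched constant-uncertainty plant
#'
#' Runs the noise-free loop on a plant identical to the design model with a
#' constant matched input disturbance f, the one scenario in which the
#' adaptive law's Lyapunov argument is exact: the uncertainty enters
#' through (B, D) exactly as the control does, the true model-frame state
#' is available, and the ideal coefficients are Theta = (-f, 0, ..., 0)
#' (the constant regressor term absorbs f). Returns the Lyapunov candidate
#' V(t) = e_x' P_err e_x + ||Theta_hat - Theta||^2 / gamma along the
#' trajectory; V must be non-increasing up to integration tolerance.
#'
#' @param design A [controller_design()].
#' @param f_const Constant disturbance in um.
#' @param command A [loading_command()].
#' @return Tibble with `t_s`, `V`, `ex1`, `ex2`.
#' @export
lyapunov_diagnostic <- function(design, f_const = 0.5,
                                command = loading_command(n_cycles = 2)) {
  stopifnot(inherits(design, "controller_design"))
  m <- design$model
  period <- 1 / command$frequency_Hz
  dt <- closed_loop_dt(m$params$tau, period, design$A_ref)
  nstep <- ceiling(command$n_cycles * period / dt)
  cmd <- command$f
  A <- m$A; B <- as.numeric(m$B); Dm <- m$D[2, 1]
  Kx1 <- design$Kx[1, 1]; Kx2 <- design$Kx[1, 2]
  Aref <- design$A_ref
  L1 <- design$L_obs[1, ]; L2 <- design$L_obs[2, ]
  gPB <- design$gamma * as.numeric(design$P_err %*% design$B_LD)
  nb <- 1 + 2 * design$basis_order
  ord <- design$basis_order
  P <- design$P_err
  Th_true <- c(-f_const, numeric(nb - 1))
  x1p <- 0; x2p <- 0; xr1 <- 0; xr2 <- 0; Th <- numeric(nb)
  zmin <- c(-1e-6, -1e-6); zmax <- c(1e-6, 1e-6)
  o_t <- numeric(nstep + 1); o_V <- numeric(nstep + 1)
  o_e1 <- numeric(nstep + 1); o_e2 <- numeric(nstep + 1)
  for (k in 0:nstep) {
    t0 <- k * dt
    zmin <- pmin(zmin, c(xr1, xr2)); zmax <- pmax(zmax, c(xr1, xr2))
    zs <- 2 / (zmax - zmin); z0 <- zmin
    deriv <- function(s, tt) {
      a1 <- s[1]; a2 <- s[2]; r1 <- s[3]; r2 <- s[4]
      z1 <- min(1, max(-1, zs[1] * (r1 - z0[1]) - 1))
      z2 <- min(1, max(-1, zs[2] * (r2 - z0[2]) - 1))
      phi <- chebyshev_basis(c(z1, z2), ord)
      uad <- sum(s[5:(4 + nb)] * phi)
      u <- -(Kx1 * r1 + Kx2 * r2) + uad
      y1 <- a1; y2 <- a2 + Dm * (u + f_const)
      da1 <- a2 + B[1] * (u + f_const) - cmd(tt)
      da2 <- A[2, 2] * a2 + B[2] * (u + f_const)
      dr1 <- Aref[1, 1] * r1 + Aref[1, 2] * r2 - cmd(tt) + L1[1] * y1 + L1[2] * y2
      dr2 <- Aref[2, 1] * r1 + Aref[2, 2] * r2 + L2[1] * y1 + L2[2] * y2
      ex1 <- a1 - r1; ex2 <- a2 - r2
      dTh <- -(gPB[1] * ex1 + gPB[2] * ex2) * phi
      list(d = c(da1, da2, dr1, dr2, dTh), ex = c(ex1, ex2))
    }
    s <- c(x1p, x2p, xr1, xr2, Th)
    d1 <- deriv(s, t0)
    ex <- d1$ex
    Tht <- Th - Th_true
    o_t[k + 1] <- t0
    o_V[k + 1] <- sum(ex * (P %*% ex)) + sum(Tht^2) / design$gamma
    o_e1[k + 1] <- ex[1]; o_e2[k + 1] <- ex[2]
    d2 <- deriv(s + dt / 2 * d1$d, t0 + dt / 2)
    d3 <- deriv(s + dt / 2 * d2$d, t0 + dt / 2)
    d4 <- deriv(s + dt * d3$d, t0 + dt)
    s <- s + dt / 6 * (d1$d + 2 * d2$d + 2 * d3$d + d4$d)
    x1p <- s[1]; x2p <- s[2]; xr1 <- s[3]; xr2 <- s[4]; Th <- s[5:(4 + nb)]
  }
  tibble::tibble(t_s = o_t, V = o_V, ex1 = o_e1, ex2 = o_e2)
}

#' Write a closed-loop trace to CSV
#'
#' Columns: `t_s,F_cmd_uN,F_f_uN,L_m_um,u_tip_um,u_bl,u_ad`.
#'
#' @param trace A `closed_loop_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(
    trace[c("t_s", "F_cmd_uN", "F_f_uN", "L_m_um", "u_tip_um", "u_bl", "u_ad")],
    path)
  invisible(path)
}

#' Read a closed-loop trace CSV
#'
#' @param path CSV path with at least the columns written by
#'   [write_trace_csv()].
#' @return Tibble (class `closed_loop_trace`).
#' @export
read_trace_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols())
  req <- c("t_s", "F_cmd_uN", "F_f_uN", "L_m_um", "u_tip_um")
  miss <- setdiff(req, names(out))
  if (length(miss)) {
    stop("trace file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("closed_loop_trace", class(out))
  out
}
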