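# Linear-algebra design blocks for the adaptive force controller: Riccati
# and Lyapunov solvers, observer pole placement, and assembly of the
# reference model. All matrices are small (2x2) and dense.

#' Solve the continuous-time algebraic Riccati equation
#'
#' A'P + PA - P B R^-1 B' P + Q = 0, solved by the stable invariant
#' subspace of the Hamiltonian matrix.
#'
#' @param A,B State and input matrices.
#' @param Q State weight (symmetric positive semi-definite).
#' @param R Input weight (symmetric positive definite).
#' @return The symmetric stabilising solution P.
#' @keywords internal
solve_care <- function(A, B, Q, R) {
  n <- nrow(A)
  H <- rbind(cbind(A, -B %*% solve(R, t(B))),
             cbind(-Q, -t(A)))
  e <- eigen(H)
  idx <- which(Re(e$values) < 0)
  if (length(idx) != n) {
    stop("Hamiltonian matrix has no n-dimensional stable subspace; ",
         "check stabilisability/detectability", call. = FALSE)
  }
  V <- e$vectors[, idx, drop = FALSE]
  P <- Re(V[(n + 1):(2 * n), , drop = FALSE] %*%
            solve(V[1:n, , drop = FALSE]))
  (P + t(P)) / 2
}

#' Solve the continuous Lyapunov equation A'P + PA = -Q
#'
#' Direct Kronecker-product vectorised solve; adequate for the 2x2 systems
#' used here.
#'
#' @param A Hurwitz matrix.
#' @param Q Symmetric positive-definite right-hand side.
#' @return Symmetric solution P.
#' @export
solve_lyapunov <- function(A, Q) {
  n <- nrow(A)
  M <- kronecker(diag(n), t(A)) + kronecker(t(A), diag(n))
  P <- matrix(solve(M, -as.vector(Q)), n, n)
  (P + t(P)) / 2
}

obsv_matrix <- function(A, C) {
  n <- nrow(A)
  blocks <- vector("list", n)
  blocks[[1]] <- C
  for (k in 2:n) blocks[[k]] <- blocks[[k - 1]] %*% A
  do.call(rbind, blocks)
}

#' Design a Luenberger observer gain
#'
#' Places the eigenvalues of A - L C at `poles`. When C is square and
#' invertible (the augmented force plant measures both the error integral
#' and the force), the gain is built from the real Schur form of A with its
#' diagonal replaced by the requested poles, L = (A - A_des) C^-1; this
#' yields L = 0 when the requested poles coincide with the plant's own.
#' For a single output, Ackermann's formula is used.
#'
#' @param model An [to_state_space()] realisation (or any list with A, C).
#' @param poles Desired observer eigenvalues (real, one per state).
#' @return The observer gain matrix `L_obs` (n x p) with attribute
#'   `achieved_poles`.
#' @export
design_observer <- function(model, poles) {
  A <- model$A; C <- model$C
  n <- nrow(A)
  if (length(poles) != n) stop("need one pole per state", call. = FALSE)
  Ob <- obsv_matrix(A, C)
  r <- qr(Ob)$rank
  if (r < n) {
    # name the deficient mode: eigenvector of A in the null space direction
    ev <- eigen(t(A))
    unob <- which(apply(abs(C %*% Re(eigen(A)$vectors)), 2, max) < 1e-10)
    stop(sprintf(
      "(A, C) is unobservable (observability rank %d < %d); unobservable mode(s): %s",
      r, n,
      paste(format(eigen(A)$values[unob]), collapse = ", ")), call. = FALSE)
  }
  if (nrow(C) == n && abs(det(C)) > 1e-12) {
    sc <- Matrix::Schur(A)
    Tm <- as.matrix(sc$T)
    ordT <- order(diag(Tm)); ordp <- order(Re(poles))
    diag(Tm)[ordT] <- Re(poles)[ordp]
    Ades <- as.matrix(sc$Q) %*% Tm %*% t(as.matrix(sc$Q))
    L <- (A - Ades) %*% solve(C)
  } else if (nrow(C) == 1) {
    # Ackermann via duality
    coefs <- Re(coef_from_roots(poles))
    phiA <- matrix(0, n, n)
    Apow <- diag(n)
    for (k in seq_along(coefs)) {
      phiA <- phiA + coefs[k] * Apow
      Apow <- Apow %*% A
    }
    phiA <- phiA + Apow  # leading monic term
    en <- matrix(0, n, 1); en[n, 1] <- 1
    L <- phiA %*% solve(Ob, en)
  } else {
    stop("unsupported C shape for pole placement", call. = FALSE)
  }
  structure(L, achieved_poles = eigen(A - L %*% C)$values)
}

coef_from_roots <- function(r) {
  # ascending coefficients of monic polynomial with roots r, constant first
  p <- 1
  for (rt in r) p <- c(0, p) - c(rt * p, 0)
  p[-length(p)]
}

#' Design the LQR baseline feedback gain
#'
#' Minimises the quadratic cost with state weight Q and input weight R for
#' the augmented plant; the baseline control is u_bl = -K_x' x_ro.
#'
#' @param model An [to_state_space()] realisation.
#' @param Q 2x2 symmetric positive-definite state weight.
#' @param R Positive scalar input weight.
#' @return List with `Kx` (1 x n gain), `P` (Riccati solution) and
#'   `closed_loop_eig`.
#' @export
design_lqr <- function(model, Q = diag(c(10, 1)), R = 1) {
  A <- model$A; B <- model$B
  Q <- as.matrix(Q)
  if (!isTRUE(all.equal(Q, t(Q))) || any(eigen(Q, symmetric = TRUE)$values <= 0)) {
    stop("Q must be symmetric positive definite", call. = FALSE)
  }
  if (!is.numeric(R) || length(R) != 1 || R <= 0) {
    stop("R must be a positive scalar", call. = FALSE)
  }
  P <- solve_care(A, B, Q, matrix(R))
  Kx <- solve(matrix(R), t(B) %*% P)   # 1 x n
  eig <- eigen(A - B %*% Kx)$values
  if (any(Re(eig) >= 0)) stop("LQR closed loop not Hurwitz", call. = FALSE)
  list(Kx = Kx, P = P, closed_loop_eig = eig)
}

#' Assemble the reference model and Lyapunov matrices
#'
#' A_ref = A - L C - (B - L D) K_x' is the closed reference dynamics
#' obtained by substituting the baseline law into the observer. Two
#' Lyapunov solutions are carried: `P_ref` certifying A_ref (the classical
#' reference-model certificate) and `P_err` solving the equation for
#' A - L C, the matrix that actually governs the state error
#' e_x = x_bar - x_ro when the baseline feeds back the observer state; the
#' adaptive law uses `P_err` (see the methods vignette).
#'
#' @param model An [to_state_space()] realisation.
#' @param L_obs Observer gain from [design_observer()].
#' @param Kx LQR gain (1 x n) from [design_lqr()].
#' @param Q_ref Symmetric positive-definite Lyapunov weight (default I).
#' @return List with `A_ref`, `C_ref`, `P_ref`, `P_err`, `Q_ref`, `B_LD`.
#' @export
build_reference_model <- function(model, L_obs, Kx, Q_ref = diag(2)) {
  A <- model$A; B <- model$B; C <- model$C; D <- model$D
  L_obs <- as.matrix(L_obs)
  Kx <- matrix(Kx, 1)
  A_ref <- A - L_obs %*% C - (B - L_obs %*% D) %*% Kx
  re <- Re(eigen(A_ref)$values)
  if (any(re > 1e-12)) {
    stop("A_ref is not Hurwitz; redo the observer/LQR design", call. = FALSE)
  }
  hurwitz <- all(re < -1e-12)
  if (!hurwitz) {
    warning("A_ref is only marginally stable; Lyapunov certificates unavailable")
  }
  A_lc <- A - L_obs %*% C
  list(A_ref = A_ref,
       C_ref = C - D %*% Kx,
       P_ref = if (hurwitz) solve_lyapunov(A_ref, Q_ref),
       P_err = if (all(Re(eigen(A_lc)$values) < -1e-12))
         solve_lyapunov(A_lc, Q_ref),
       Q_ref = Q_ref,
       B_LD = B - L_obs %*% D)
}

#' Full controller design for the cyclic-stretching force loop
#'
#' Bundles observer, LQR baseline, reference model and adaptation
#' configuration. Defaults (state weight favouring the force-error
#' integral, observer poles 20-30x the plant relaxation rate, adaptation
#' rate gamma = 0.001 on a 3rd-order Chebyshev basis) are the package's
#' calibrated operating point for soft-microfiber plants; all are
#' overridable here or via the config file.
#'
#' @param model An [to_state_space()] realisation of the design plant.
#' @param Q,R LQR weights (see [design_lqr()]).
#' @param observer_poles Observer eigenvalues; default c(-20, -30)/tau.
#' @param Q_ref Lyapunov weight for the reference model (default I).
#' @param gamma Scalar adaptation rate (Gamma = gamma I).
#' @param basis_order Chebyshev order per observer state (default 3).
#' @return An object of class `controller_design`.
#' @export
controller_design <- function(model, Q = diag(c(10, 1)), R = 1,
                              observer_poles = NULL, Q_ref = diag(2),
                              gamma = 0.001, basis_order = 3) {
  stopifnot(inherits(model, "sls_state_space"))
  tau <- model$params$tau
  if (is.null(observer_poles)) observer_poles <- c(-20, -30) / tau
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  L_obs <- design_observer(model, observer_poles)
  lqr <- design_lqr(model, Q, R)
  ref <- build_reference_model(model, L_obs, lqr$Kx, Q_ref)
  structure(list(model = model,
                 L_obs = L_obs,
                 Kx = lqr$Kx,
                 riccati_P = lqr$P,
                 A_ref = ref$A_ref, C_ref = ref$C_ref,
                 P_ref = ref$P_ref, P_err = ref$P_err,
                 Q_ref = ref$Q_ref, B_LD = ref$B_LD,
                 gamma = gamma, basis_order = basis_order,
                 Q = Q, R = R, observer_poles = observer_poles),
            class = "controller_design")
}

#' @export
print.controller_design <- function(x, ...) {
  cat("<controller_design>\n")
  cat("  Kx:", format(as.numeric(x$Kx), digits = 4), "\n")
  cat("  observer poles:", format(x$observer_poles, digits = 4), "\n")
  cat("  eig(A_ref):", format(eigen(x$A_ref)$values, digits = 4), "\n")
  cat("  gamma:", x$gamma, " basis order:", x$basis_order, "\n")
  invisible(x)
}

#' Serialise a controller design to JSON
#'
#' @param design A [controller_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "controller_design"))
  jsonlite::write_json(list(
    Kx = as.numeric(design$Kx),
    L_obs = as.numeric(design$L_obs),
    A_ref = as.numeric(design$A_ref),
    P_ref = as.numeric(design$P_ref),
    P_err = as.numeric(design$P_err),
    gamma = design$gamma,
    basis_order = design$basis_order,
    observer_poles = design$observer_poles,
    plant = list(lambda1 = design$model$params$lambda1,
                 lambda2 = design$model$params$lambda2,
                 tau = design$model$params$tau)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
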