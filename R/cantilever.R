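#' Geometry of the force-sensing cantilever tube
#'
#' The sensing tube is a glass cantilever clamped at one end; the microfiber
#' is glued to it at axial position `attach_mm` (0 at the clamp, `length_mm`
#' at the free tip). Pulling the fiber bends the tube, and the tip deflection
#' read by the microscope is converted to force through the Euler-Bernoulli
#' beam model.
#'
#' @param length_mm Tube length L in mm.
#' @param attach_mm Axial glue position x_a in mm, with 0 < x_a <= L.
#' @param modulus_Pa Elastic modulus E_t of the tube material in Pa.
#' @param inertia_m4 Second moment of area I_z of the tube cross-section in
#'   m^4.
#' @return An object of class `tube_geometry`.
#' @examples
#' geom <- tube_geometry(70, 60, 70e9, 1e-12)
#' tip_deflection(10, geom)
#' @export
tube_geometry <- function(length_mm, attach_mm, modulus_Pa, inertia_m4) {
  vals <- c(length_mm = length_mm, attach_mm = attach_mm,
            modulus_Pa = modulus_Pa, inertia_m4 = inertia_m4)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all tube geometry fields must be finite and strictly positive",
         call. = FALSE)
  }
  if (attach_mm > length_mm) {
    stop("attach_mm must not exceed length_mm", call. = FALSE)
  }
  structure(as.list(vals), class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf(
    "<tube_geometry> L = %g mm, x_a = %g mm, E_t = %g Pa, I_z = %g m^4\n",
    x$length_mm, x$attach_mm, x$modulus_Pa, x$inertia_m4))
  invisible(x)
}

#' Tip deflection of the sensing tube under a point load at the glue position
#'
#' Euler-Bernoulli cantilever with a point load F applied at x_a gives a tip
#' deflection of magnitude
#' \deqn{u_{tip} = \frac{F x_a^2 (3L - x_a)}{6 E_t I_z}.}
#' Magnitudes are returned; the deflection direction (opposing the pull) is
#' tracked separately by callers where it matters.
#'
#' @param force_uN Applied force in micro-newtons (vectorised, must be >= 0).
#' @param geom A [tube_geometry()].
#' @return Tip deflection in micro-metres.
#' @export
tip_deflection <- function(force_uN, geom) {
  stopifnot(inherits(geom, "tube_geometry"))
  if (any(!is.finite(force_uN)) || any(force_uN < 0)) {
    stop("force_uN must be finite and non-negative", call. = FALSE)
  }
  F_N <- force_uN * 1e-6
  L <- geom$length_mm * 1e-3
  xa <- geom$attach_mm * 1e-3
  u_m <- F_N * xa^2 * (3 * L - xa) / (6 * geom$modulus_Pa * geom$inertia_m4)
  u_m * 1e6
}

#' Tip-referred stiffness of the sensing tube
#'
#' The constant K relating the stretching force to the observed tip
#' deflection, K = F / u_tip = 6 E_t I_z / (3 L x_a^2 - x_a^3), expressed in
#' uN/um.
#'
#' @param geom A [tube_geometry()].
#' @return An object of class `tube_stiffness` with fields `K_uN_per_um`,
#'   `fit_param_a` (here the exact E_t I_z product, in N m^2) and `r2`
#'   (NA: no fit involved).
#' @export
stiffness_from_geometry <- function(geom) {
  stopifnot(inherits(geom, "tube_geometry"))
  u_per_F <- tip_deflection(1, geom)  # um per uN
  new_tube_stiffness(K = 1 / u_per_F,
                     fit_param_a = geom$modulus_Pa * geom$inertia_m4,
                     r2 = NA_real_)
}

new_tube_stiffness <- function(K, fit_param_a, r2) {
  if (!is.finite(K) || K <= 0) stop("stiffness K must be positive", call. = FALSE)
  if (is.finite(r2) && r2 > 1) stop("r2 cannot exceed 1", call. = FALSE)
  structure(list(K_uN_per_um = K, fit_param_a = fit_param_a, r2 = r2),
            class = "tube_stiffness")
}

#' @export
print.tube_stiffness <- function(x, ...) {
  cat(sprintf("<tube_stiffness> K = %.6g uN/um", x$K_uN_per_um))
  if (is.finite(x$r2)) cat(sprintf(" (calibration R^2 = %.4f)", x$r2))
  cat("\n")
  invisible(x)
}

#' Convert an observed tip deflection to a stretching force
#'
#' F_f = K * u_tip. Negative deflections (tube pushed instead of pulled) are
#' allowed; the result then carries a `compression` attribute.
#'
#' @param u_tip_um Tip deflection in um (vectorised).
#' @param K Tip stiffness in uN/um, or a `tube_stiffness`.
#' @return Force in uN, with attribute `compression` flagging negative input.
#' @export
force_from_tip_deflection <- function(u_tip_um, K) {
  if (inherits(K, "tube_stiffness")) K <- K$K_uN_per_um
  if (!is.finite(K) || K <= 0) stop("K must be a positive scalar", call. = FALSE)
  out <- K * u_tip_um
  if (any(u_tip_um < 0, na.rm = TRUE)) {
    attr(out, "compression") <- u_tip_um < 0
  }
  out
}

#' Calibrate the tube stiffness from reference-scale measurements
#'
#' Each record holds a force read from a precision balance and the deflection
#' u_a of the tube at the contact position x_a. The body-point stiffness
#' K_a = F/u_a is referred to the tip through the geometric factor
#' 2 x_a / (3L - x_a), and the one-parameter family
#' \deqn{K(x_a) = \frac{6a}{3 L x_a^2 - x_a^3}}
#' is then fitted by least squares for `a` (which plays the role of the
#' bending rigidity E_t I_z). The returned stiffness is evaluated at
#' `attach_mm` (default: the largest calibrated x_a).
#'
#' @param records Data frame with columns `x_a_mm`, `force_uN`,
#'   `deflection_um` (deflection measured at x_a).
#' @param length_mm Tube length L in mm.
#' @param attach_mm Position at which to report K; defaults to max(x_a).
#' @return A `tube_stiffness` with the fitted `a` and the R^2 of the fit,
#'   plus a `tip_stiffness_fun` attribute giving K(x_a).
#' @export
calibrate_stiffness <- function(records, length_mm, attach_mm = NULL) {
  req <- c("x_a_mm", "force_uN", "deflection_um")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[req]
  if (any(records$force_uN <= 0) || any(records$deflection_um <= 0)) {
    stop("forces and deflections must be strictly positive", call. = FALSE)
  }
  xa <- records$x_a_mm
  if (length(xa) < 3 || length(unique(xa)) < 3) {
    stop("need at least 3 records at 3 distinct x_a positions", call. = FALSE)
  }
  if (any(xa <= 0) || any(xa > length_mm)) {
    stop("x_a_mm must lie in (0, length_mm]", call. = FALSE)
  }
  L <- length_mm
  # tip-referred stiffness observed at each record
  K_obs <- 2 * xa / (3 * L - xa) * records$force_uN / records$deflection_um
  g <- 6 / (3 * L * xa^2 - xa^3)           # K = a * g
  a_hat <- sum(g * K_obs) / sum(g^2)       # least squares, single parameter
  K_fit <- a_hat * g
  ss_res <- sum((K_obs - K_fit)^2)
  ss_tot <- sum((K_obs - mean(K_obs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (is.null(attach_mm)) attach_mm <- max(xa)
  K_fun <- function(x) 6 * a_hat / (3 * L * x^2 - x^3)
  out <- new_tube_stiffness(K = K_fun(attach_mm), fit_param_a = a_hat, r2 = r2)
  attr(out, "tip_stiffness_fun") <- K_fun
  out
}

#' Generate synthetic calibration records from a known tube
#'
#' Emulates the balance calibration: the tube is pressed on a reference prism
#' at several positions x_a, and (force, local deflection) pairs are logged.
#' Deflections follow the beam model u_a = F x_a^3 / (3 E_t I_z), optionally
#' with multiplicative Gaussian noise.
#'
#' @param geom A [tube_geometry()] (its `attach_mm` is ignored here).
#' @param x_a_mm Vector of contact positions in mm.
#' @param force_uN Applied force(s) in uN (recycled against `x_a_mm`).
#' @param rel_noise Multiplicative noise sd on the deflection (0 = exact).
#' @param seed Optional seed for reproducibility.
#' @return Tibble with columns `x_a_mm`, `force_uN`, `deflection_um`.
#' @export
synthetic_calibration_records <- function(geom, x_a_mm, force_uN = 10,
                                          rel_noise = 0, seed = NULL) {
  stopifnot(inherits(geom, "tube_geometry"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(x_a_mm)
  force_uN <- rep_len(force_uN, n)
  EI <- geom$modulus_Pa * geom$inertia_m4
  u_m <- (force_uN * 1e-6) * (x_a_mm * 1e-3)^3 / (3 * EI)
  u_um <- u_m * 1e6
  if (rel_noise > 0) u_um <- u_um * (1 + stats::rnorm(n, 0, rel_noise))
  tibble::tibble(x_a_mm = x_a_mm, force_uN = force_uN, deflection_um = u_um)
}

#' Read calibration records from CSV
#'
#' Expects the header `x_a_mm,force_uN,deflection_um`.
#'
#' @param path CSV file path.
#' @return Tibble of calibration records.
#' @export
read_calibration_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    x_a_mm = readr::col_double(),
    force_uN = readr::col_double(),
    deflection_um = readr::col_double()
  ))
}

#' Serialise a tube stiffness to JSON
#'
#' @param x A `tube_stiffness`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stiffness_json <- function(x, path) {
  stopifnot(inherits(x, "tube_stiffness"))
  jsonlite::write_json(
    list(K_uN_per_um = x$K_uN_per_um, fit_param_a = x$fit_param_a, r2 = x$r2),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
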