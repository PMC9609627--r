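#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a closed-loop force-tracking trace
#'
#' Commanded and realised force against time, with the control components
#' in a second panel.
#'
#' @param object A `closed_loop_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.closed_loop_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[c("t_s", "F_cmd_uN", "F_f_uN")],
    cols = c("F_cmd_uN", "F_f_uN"),
    names_to = "signal", values_to = "force_uN")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$force_uN,
                                   colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(F_cmd_uN = "grey40", F_f_uN = "#D55E00"),
      labels = c(F_cmd_uN = "command", F_f_uN = "realised")) +
    ggplot2::labs(x = "time (s)", y = "force (µN)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the Lissajous stress-strain loop
#'
#' Parametric ellipse reconstructed from the fitted sinusoids, with the
#' long axis drawn through the origin-centred loop.
#'
#' @param object A `lissajous_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lissajous_result <- function(object, ...) {
  th <- seq(0, 2 * pi, length.out = 361)
  lag <- object$phase_lag_rad
  e0 <- object$strain_fit$amplitude
  s0 <- object$stress_fit$amplitude
  df <- tibble::tibble(strain = e0 * sin(th), stress_kPa = s0 * sin(th + lag))
  ax <- tibble::tibble(strain = c(-object$L_x, object$L_x),
                       stress_kPa = c(-object$L_y, object$L_y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain, y = .data$stress_kPa)) +
    ggplot2::geom_path(colour = "#0072B2") +
    ggplot2::geom_line(data = ax, linetype = 2, colour = "grey50") +
    ggplot2::annotate("text", x = object$L_x, y = object$L_y,
                      label = sprintf("E_c = %.3g kPa", object$E_c_kPa),
                      hjust = -0.05, vjust = 0) +
    ggplot2::labs(x = "strain (centred)", y = "stress (kPa, centred)") +
    ggplot2::theme_minimal()
}

#' Plot a stiffness calibration against its fitted curve
#'
#' @param records Calibration records (as for [calibrate_stiffness()]).
#' @param stiffness The `tube_stiffness` returned by the calibration.
#' @param length_mm Tube length used in the calibration.
#' @return A ggplot object.
#' @export
plot_calibration <- function(records, stiffness, length_mm) {
  K_fun <- attr(stiffness, "tip_stiffness_fun")
  stopifnot(!is.null(K_fun))
  xa <- records$x_a_mm
  obs <- tibble::tibble(
    x_a_mm = xa,
    K = 2 * xa / (3 * length_mm - xa) * records$force_uN / records$deflection_um)
  grid <- tibble::tibble(x_a_mm = seq(min(xa), max(xa), length.out = 200))
  grid$K <- K_fun(grid$x_a_mm)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$x_a_mm, y = .data$K)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#0072B2") +
    ggplot2::labs(x = "glue position x_a (mm)",
                  y = "tip stiffness K (µN/µm)",
                  subtitle = sprintf("R² = %.4f", stiffness$r2)) +
    ggplot2::theme_minimal()
}
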