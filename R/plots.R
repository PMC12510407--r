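# ggplot2 methods for the package's result types

#' Plot a cosinor fit over its actigraphy trace
#'
#' @param object A `chp_cosinor` fit.
#' @param ... Unused.
#' @return A ggplot object: per-minute METs folded onto the day with the
#'   fitted cosinor curve overlaid.
#' @export
autoplot.chp_cosinor <- function(object, ...) {
  grid <- tibble(minute_of_day = seq(0, 1439, by = 2))
  grid$met <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$minute_of_day / 60, y = .data$met)) +
    ggplot2::geom_point(alpha = 0.1, size = 0.3) +
    ggplot2::geom_line(data = grid, colour = "#d55e00", linewidth = 1) +
    ggplot2::labs(x = "Time of day (h)", y = "Energy expenditure (MET)",
                  title = sprintf("Cosinor fit: amplitude %.2f MET, acrophase %.2f rad",
                                  object$amplitude, object$acrophase_rad))
}

#' Plot the white-matter-density sensitivity line
#'
#' @param object A `chp_wm_sensitivity` table from [wm_sensitivity()].
#' @param ... Unused.
#' @return A ggplot object showing the exactly linear dependence of the
#'   calculated ChP density on the assumed WM density, with the 0.70
#'   calibration point marked.
#' @export
autoplot.chp_wm_sensitivity <- function(object, ...) {
  ratio <- attr(object, "si_ratio")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rho_wm, y = .data$rho_chp)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0.70, linetype = "dashed") +
    ggplot2::labs(x = "Assumed WM water density (mL/mL)",
                  y = "Calculated ChP water density (mL/mL)",
                  title = sprintf("Slope = measured signal ratio = %.3f", ratio))
}

#' Plot the perfusion-error sweep
#'
#' @param object A `chp_perfusion_sweep` from [perfusion_error_sweep()].
#' @param ... Unused.
#' @return A ggplot object of calculated vs actual perfusion with the
#'   identity line, plus the absolute error.
#' @export
autoplot.chp_perfusion_sweep <- function(object, ...) {
  rho <- attr(object, "rho")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f_actual)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f_calc), colour = "#0072b2") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$abs_error), colour = "#d55e00") +
    ggplot2::labs(x = "Actual perfusion (mL/100 g/min)",
                  y = "Calculated perfusion / |error| (mL/100 g/min)",
                  title = sprintf("Assumed rho = %.3f vs true rho = %.3f",
                                  rho[["assumed"]], rho[["true"]]))
}

#' Densities by epoch for a quantified cohort
#'
#' @param densities Output of [quantify_cohort()].
#' @return A ggplot object: per-scan quantified densities by epoch with
#'   per-epoch means, in the style of a repeated-measures summary figure.
#' @export
plot_density_by_epoch <- function(densities) {
  circ <- dplyr::filter(densities, .data$scan_type == "circadian")
  ggplot2::ggplot(circ, ggplot2::aes(x = factor(.data$epoch),
                                     y = .data$rho_chp)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "#d55e00") +
    ggplot2::labs(x = "Scan epoch", y = "ChP water density (mL/mL)")
}
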