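#' Displacement-versus-clearance curves
#'
#' One line per archwire codename for a chosen column of a
#' reference-shaped table.
#'
#' @param records A reference-shaped tibble (see
#'   [reference_displacements()]).
#' @param column `"calculated"`, `"simulated"` or `"experimental"`.
#' @return A ggplot object.
#' @export
plot_displacement_curves <- function(records = reference_displacements(),
                                     column = c("experimental",
                                                "calculated", "simulated")) {
  column <- match.arg(column)
  col <- paste0(column, "_mm")
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$clearance_mm, y = .data[[col]],
                               colour = .data$codename)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Clearance distance b (mm)",
                  y = paste0(column, " displacement (mm)"),
                  colour = "Archwire") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a deviation report
#'
#' Per-record model-versus-experiment deviation rate against clearance
#' distance, coloured by codename.
#'
#' @param object A [deviation_report()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tloop_deviation_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$clearance_mm,
                               y = .data$deviation_pct,
                               colour = .data$codename)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Clearance distance b (mm)",
                  y = "Deviation rate (%)", colour = "Archwire") +
    ggplot2::theme_minimal()
}

#' Plot calibration residuals
#'
#' Residuals of a [fit_parameters()] fit against the fitted displacement.
#'
#' @param object A `tloop_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tloop_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$fitted_mm, y = .data$residual_mm,
                               colour = .data$codename)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Fitted displacement (mm)", y = "Residual (mm)",
                  colour = "Archwire") +
    ggplot2::theme_minimal()
}
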