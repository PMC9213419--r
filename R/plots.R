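#' Bland-Altman plot
#'
#' @param ba Result of [bland_altman()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = "Bland-Altman") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(ba$points, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, color = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(title = title, x = "Mean of methods",
                  y = "Difference (test - reference)") +
    ggplot2::theme_minimal()
}

#' Calibration-curve plot for the hemoglobin strip
#'
#' @param model A [fit_hb_calibration()] model.
#' @param standards Optional standards data.frame (hb, value) to overlay.
#' @return A ggplot object.
#' @export
plot_hb_calibration <- function(model, standards = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  grid <- data.frame(hb = seq(model$hb_range[1], model$hb_range[2],
                              length.out = 200))
  grid$value <- predict_color(model, grid$hb)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = hb, y = value)) +
    ggplot2::geom_line(color = "blue") +
    ggplot2::labs(x = "HB (g/dL)", y = "Mean colorimetric value") +
    ggplot2::theme_minimal()
  if (!is.null(standards))
    p <- p + ggplot2::geom_point(data = standards, color = "black")
  p
}
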