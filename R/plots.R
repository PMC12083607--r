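# ggplot2 helpers for regions and model fits.

#' Overlay ROI and control ellipses on a thermal image
#'
#' @param thermal Thermal matrix, degrees C.
#' @param roi,control [roi_ellipse()] objects (`control` optional).
#' @return A ggplot: temperature raster with ellipse outlines.
#' @export
plot_region_overlay <- function(thermal, roi, control = NULL) {
  df <- tidyr::expand_grid(row = 0:(nrow(thermal) - 1),
                           col = 0:(ncol(thermal) - 1))
  df$temp <- as.numeric(t(thermal))
  outline <- function(e, label) {
    dplyr::mutate(ellipse_points(e, seq(0, 2 * pi, length.out = 181)),
                  region = label)
  }
  rings <- dplyr::bind_rows(
    outline(roi, "roi"),
    if (!is.null(control)) outline(control, "control")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$temp)) +
    ggplot2::geom_path(
      data = rings,
      ggplot2::aes(x = .data$col, y = .data$row, linetype = .data$region),
      color = "white", linewidth = 0.7, inherit.aes = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "deg C") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = "Thermal image with cooling ROI and control region")
}

#' Coefficient plot for a fitted thermal mixed model
#'
#' @param object A `thermo_model`.
#' @param ... Unused.
#' @return A ggplot of fixed-effect estimates with approximate 95% intervals.
#' @method autoplot thermo_model
#' @export
autoplot.thermo_model <- function(object, ...) {
  t <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(t, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(
      x = "estimate (deg C)", y = NULL,
      title = sprintf("Fixed effects: %s model, %s response",
                      object$model_label, object$response_label))
}

#' Cooling-summary plot
#'
#' @param object A `cooling_summary` from [summarize_cooling()].
#' @param ... Unused.
#' @return A ggplot of region means by measure with SD bars.
#' @method autoplot cooling_summary
#' @export
autoplot.cooling_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$measure, y = .data$mean,
                               fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::labs(x = NULL, y = "median temperature (deg C)",
                  title = "Cooling response by region")
}
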