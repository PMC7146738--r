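# Figures: filled-contour interaction map with measured/predicted
# anchors, and the reduction-ratio scatter colored by mixture intensity.

surface_long <- function(surface) {
  res_a <- length(surface$axis_a)
  res_b <- length(surface$axis_b)
  tibble::tibble(
    lnoav_a = rep(surface$axis_a, times = res_b),
    lnoav_b = rep(surface$axis_b, each = res_a),
    oi_mix = as.vector(surface$oi_mix),
    oi_sum = as.vector(surface$oi_sum),
    oi_reduction = as.vector(surface$oi_reduction),
    masked = as.vector(surface$mask)
  )
}

#' Contour map of the OI reduction over the lnOAV plane
#'
#' Masked cells (OI_sum below the exclusion threshold) are left blank,
#' reproducing the empty low-intensity corner of the composition maps.
#' Measured samples are overlaid in red, grid predictions in black.
#'
#' @param surface An [simulate_interaction_surface()] result.
#' @param show_anchors Overlay measured/predicted points (default TRUE).
#' @return A ggplot object.
#' @export
plot_interaction_surface <- function(surface, show_anchors = TRUE) {
  df <- surface_long(surface)
  df$oi_reduction[df$masked] <- NA_real_
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$lnoav_a, y = .data$lnoav_b, z = .data$oi_reduction)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$oi_reduction)) +
    ggplot2::geom_contour(color = "grey30", na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(na.value = "transparent",
                                  name = "OI reduction") +
    ggplot2::labs(
      x = bquote("lnOAV of" ~ .(surface$pair[1])),
      y = bquote("lnOAV of" ~ .(surface$pair[2])),
      title = sprintf("Odor interaction: %s + %s",
                      surface$pair[1], surface$pair[2])) +
    ggplot2::theme_minimal()
  if (show_anchors) {
    anchors <- surface$anchors
    p <- p +
      ggplot2::geom_point(
        data = anchors[anchors$source == "predicted", ],
        ggplot2::aes(x = .data$lnoav_a, y = .data$lnoav_b),
        inherit.aes = FALSE, color = "black", size = 0.1, alpha = 0.3) +
      ggplot2::geom_point(
        data = anchors[anchors$source == "measured", ],
        ggplot2::aes(x = .data$lnoav_a, y = .data$lnoav_b),
        inherit.aes = FALSE, color = "red", size = 1.6)
  }
  p
}

#' Scatter of reduction ratio vs mixing ratio
#'
#' @param scatter A [ratio_scatter()] tibble.
#' @return A ggplot object; color encodes the mixture intensity.
#' @export
plot_ratio_scatter <- function(scatter) {
  ggplot2::ggplot(scatter, ggplot2::aes(
    x = .data$x_a, y = .data$oi_reduction_ratio,
    color = .data$oi_mix, shape = .data$source)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_color_viridis_c(name = "OI_mix (OIRS)") +
    ggplot2::labs(x = expression(x[a] == lnOAV[a] / (lnOAV[a] + lnOAV[b])),
                  y = "OI reduction ratio") +
    ggplot2::theme_minimal()
}
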