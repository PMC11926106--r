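#' Phasor-plot visualisation
#'
#' 2-D bin plot of the included pixels' (G, S) coordinates with the unit
#' circle for reference; optionally overlays a trajectory axis.
#'
#' @param object A `phasor_field` tibble from [phasor_transform()].
#' @param axis Optional [trajectory_axis()] to draw.
#' @param bins Number of 2-D bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phasor_field <- function(object, axis = NULL, bins = 120, ...) {
  circ <- tibble(
    t = seq(0, 2 * pi, length.out = 361),
    G = cos(seq(0, 2 * pi, length.out = 361)),
    S = sin(seq(0, 2 * pi, length.out = 361))
  )
  p <- ggplot2::ggplot(dplyr::filter(object, .data$included),
                       ggplot2::aes(x = .data$G, y = .data$S)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::geom_path(data = circ, linetype = "dashed", colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "G", y = "S", fill = "pixels") +
    ggplot2::theme_minimal()
  if (!is.null(axis)) {
    seg <- tibble(G = axis$g0, S = axis$s0, Gend = axis$g1, Send = axis$s1)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(xend = .data$Gend, yend = .data$Send),
      linetype = "dotted", colour = "white"
    )
  }
  p
}

#' Fluidity-fraction histogram plot
#'
#' @param object A [fraction_histogram()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fraction_histogram <- function(object, ...) {
  cm <- center_of_mass(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_position,
                                       y = .data$frequency)) +
    ggplot2::geom_col(width = 1 / nrow(object), fill = "steelblue") +
    ggplot2::geom_vline(xintercept = cm, linetype = "dashed") +
    ggplot2::labs(x = "fluidity fraction", y = "normalized frequency",
                  subtitle = sprintf("center of mass = %.3f", cm)) +
    ggplot2::theme_minimal()
}

#' Wetting-geometry contour plot
#'
#' Draws labeled contour points of a vesicle-condensate cross-section,
#' coloured by interface arc, with equal axis scaling.
#'
#' @param contours A data frame with `x`, `y`, `arc` columns (one image).
#' @return A ggplot object.
#' @export
plot_wetting_contours <- function(contours) {
  ggplot2::ggplot(contours, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$arc)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +  # image convention: y increases downward
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "interface") +
    ggplot2::theme_minimal()
}

#' Pipeline recovery plot
#'
#' Truth-versus-estimate scatter per stage for a [run_pipeline()] result,
#' with the identity line.
#'
#' @param object A `memwet_pipeline` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.memwet_pipeline <- function(object, ...) {
  df <- dplyr::bind_rows(
    lapply(names(object$results), function(st) {
      dplyr::mutate(object$results[[st]][c("truth", "estimate")], stage = st)
    })
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~stage, scales = "free") +
    ggplot2::labs(x = "ground truth", y = "estimate") +
    ggplot2::theme_minimal()
}
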