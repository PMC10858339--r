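#' Plot a surge profile
#'
#' Height (`-log10` p) against activation delay within the trial cycle, with
#' an optional threshold line.
#'
#' @param object A [surge_profile()].
#' @param height_threshold Optional horizontal reference line (default 2,
#'   i.e. p = .01; `NULL` for none).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surge_profile <- function(object, height_threshold = 2, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$bin_center_s, y = .data$height)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_area(alpha = 0.25) +
    ggplot2::labs(
      x = "Delay within cycle (s)",
      y = expression(-log[10](italic(p))),
      title = attr(object, "roi_name")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(height_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = height_threshold,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a phase-gradient vector field on flat coordinates
#'
#' Arrows at each valid vertex, pointing along local wave travel (or raw
#' theta-gradient, depending on the field's orientation), scaled for
#' legibility.
#'
#' @param object A [phase_gradient_field()].
#' @param mesh The [surface_mesh()] the field was computed on.
#' @param arrow_scale Arrow length per radian/mm (default chosen from the
#'   median gradient so arrows span about one edge length).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_gradient_field <- function(object, mesh, arrow_scale = NULL, ...) {
  f <- tidy(object)
  f <- f[f$valid, , drop = FALSE]
  xy <- mesh$vertex_flat[f$unit_id + 1L, , drop = FALSE]
  mag <- sqrt(f$gx^2 + f$gy^2)
  if (is.null(arrow_scale)) {
    med <- stats::median(mag[mag > 0])
    arrow_scale <- if (is.finite(med) && med > 0) 1 / med else 1
  }
  df <- tibble::tibble(
    x = xy[, 1], y = xy[, 2],
    xend = xy[, 1] + arrow_scale * f$gx,
    yend = xy[, 2] + arrow_scale * f$gy
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_segment(arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Flat x (mm)", y = "Flat y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot an activation map on flat coordinates
#'
#' Significant vertices colored by activation delay (phase mapped through
#' [phase_to_delay()]) on the flattened mesh — the static counterpart of the
#' isophase movie.
#'
#' @param map An [activation_map()] on `mesh`.
#' @param mesh A [surface_mesh()] with flat coordinates.
#' @param period_seconds Trial period for the delay scale (default 16).
#' @return A ggplot.
#' @export
plot_phase_map <- function(map, mesh, period_seconds = 16) {
  xy <- mesh$vertex_flat[map$unit_id + 1L, , drop = FALSE]
  df <- tibble::tibble(
    x = xy[, 1], y = xy[, 2],
    delay_s = phase_to_delay(map_phase(map), period_seconds)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$delay_s)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_gradientn(
      colours = grDevices::rainbow(64, end = 0.9),
      limits = c(0, period_seconds), name = "Delay (s)"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Flat x (mm)", y = "Flat y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot cycle-averaged time courses
#'
#' @param cycle_df Output of [cycle_average()].
#' @param units Optional subset of unit ids.
#' @return A ggplot of signal against time within the cycle, one line per
#'   unit.
#' @export
plot_cycle_average <- function(cycle_df, units = NULL) {
  df <- cycle_df
  if (!is.null(units)) df <- df[df$unit_id %in% units, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$signal,
                                   group = .data$unit_id,
                                   colour = factor(.data$unit_id))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time within cycle (s)",
                  y = if (isTRUE(attr(cycle_df, "percent"))) "Signal change (%)" else "Signal (a.u.)",
                  colour = "Unit") +
    ggplot2::theme_minimal()
}
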