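#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot orientation-angle traces
#'
#' Raw and smoothed per-lipid orientation angles against time, with the far
#' thresholds (35/145 degrees) and the 90-degree midline drawn as reference
#' lines.
#'
#' @param traces Tibble from [compute_angle_traces()].
#' @param lipids Optional subset of lipid ids to show.
#' @param angle_lower,angle_upper Far thresholds to draw (default 35/145).
#' @return A ggplot object.
#' @export
plot_angle_traces <- function(traces, lipids = NULL, angle_lower = 35,
                              angle_upper = 145) {
  if (!is.null(lipids)) traces <- traces[traces$lipid %in% lipids, ]
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$angle), alpha = 0.25,
                       colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$angle_smooth),
                       colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = c(angle_lower, 90, angle_upper),
                        linetype = c("dashed", "dotted", "dashed"),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~lipid) +
    ggplot2::labs(x = "time (ns)", y = "orientation angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a groove-dilation distance series
#'
#' Raw minimum TM4-TM6 distance (transparent) with its EWMA smoothing
#' (solid) and the groove-open threshold; optionally marks event completion
#' times.
#'
#' @param groove Tibble from [groove_distance_series()].
#' @param events Optional event tibble from [detect_events()].
#' @param groove_open Threshold line (A, default 6).
#' @return A ggplot object.
#' @export
plot_groove_series <- function(groove, events = NULL, groove_open = 6) {
  p <- ggplot2::ggplot(groove, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$distance), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$distance_smooth),
                       colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = groove_open, linetype = "dashed") +
    ggplot2::labs(x = "time (ns)", y = "min TM4-TM6 distance (A)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(time = events$t_complete, y = groove_open),
      ggplot2::aes(x = .data$time, y = .data$y), shape = 16, size = 1)
  }
  p
}

#' @export
#' @rdname average_surfaces
#' @param object A `leaflet_surfaces` object.
autoplot.leaflet_surfaces <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$mask_upper & df$mask_lower, ]
  df$thickness <- df$z_upper - df$z_lower
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$thickness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "thickness (A)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)") +
    ggplot2::theme_minimal()
}

#' Plot a free-energy profile
#'
#' @param pmf Tibble from [pmf_from_density()].
#' @return A ggplot object.
#' @export
plot_free_energy <- function(pmf) {
  ggplot2::ggplot(pmf[!pmf$empty, ],
                  ggplot2::aes(x = .data$s, y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "path coordinate s (A)", y = "free energy (kT)") +
    ggplot2::theme_minimal()
}
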