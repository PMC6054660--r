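# ggplot2 visualizations for trajectories and analysis results.

#' Plot a trajectory snapshot
#'
#' Draws one frame of a simulation with proteins coloured by the size of the
#' cluster they belong to.
#'
#' @param object a `meso_trajectory`.
#' @param frame frame index (default: last recorded frame).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.meso_trajectory <- function(object, frame = NULL, ...) {
  f <- traj_frame(object, frame) |>
    dplyr::add_count(.data$cluster_id, name = "cluster_size")
  box <- attr(object, "box")
  p <- ggplot2::ggplot(f, ggplot2::aes(.data$x, .data$y,
                                       colour = .data$cluster_size)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = "cluster size") +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("frame %d", unique(f$frame)))
  if (!is.null(box)) {
    p <- p + ggplot2::expand_limits(x = c(0, box[["width"]]),
                                    y = c(0, box[["height"]]))
  }
  p
}

#' Plot cluster growth over time
#'
#' Maximum cluster size and number of clusters per recorded frame.
#'
#' @param traj a `meso_trajectory`.
#' @return a ggplot object.
#' @export
plot_cluster_growth <- function(traj) {
  cs <- cluster_summary(traj) |>
    tidyr::pivot_longer(c("n_clusters", "max_cluster_size"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(cs, ggplot2::aes(.data$time_ns / 1000, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (µs)", y = NULL)
}

#' @rdname compute_msd
#' @param object an `msd_curve`.
#' @export
autoplot.msd_curve <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time_ns, .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = g$slope, intercept = g$intercept,
                         linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "lag time (ns)", y = expression(MSD ~ (nm^2)),
                  subtitle = sprintf("D = %.3g nm²/ns (%.3g µm²/s)",
                                     g$D_nm2_ns, g$D_um2_s))
}

#' @rdname neighbor_angular_density
#' @param object an `angular_density`.
#' @param ... unused.
#' @export
autoplot.angular_density <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_col(width = 360 / attr(object, "n_bins")) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::labs(x = "body-frame angle (deg)", y = "density (1/deg)")
}

#' Plot per-window motion classification
#'
#' Timeline of sliding-window labels for one protein; trajectory edges not
#' covered by a complete window appear as gaps (unclassified).
#'
#' @param x a `motion_classification`.
#' @return a ggplot object.
#' @export
plot_motion_windows <- function(x) {
  ggplot2::ggplot(x$windows,
                  ggplot2::aes(xmin = .data$start_frame,
                               xmax = .data$end_frame,
                               ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_manual(values = c(brownian = "#2ca02c",
                                          confined = "#d62728",
                                          unclassified = "grey70")) +
    ggplot2::labs(x = "frame", y = NULL,
                  title = sprintf("protein %s: %s", format(x$protein_id),
                                  x$overall)) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}
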