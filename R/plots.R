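#' Plot a kymograph
#'
#' Space-time raster with arc length (soma end at 0) on the x axis and time
#' running downward, the orientation in which sloped lines read as moving
#' vesicles.
#'
#' @param kymo An `axq_kymograph` from [extract_kymograph()].
#' @return A ggplot object.
#' @export
plot_kymograph <- function(kymo) {
  stopifnot(inherits(kymo, "axq_kymograph"))
  bin <- attr(kymo, "bin_size_um")
  dt <- attr(kymo, "frame_interval")
  df <- tidyr::expand_grid(frame = seq_len(nrow(kymo)),
                           bin = seq_len(ncol(kymo)))
  df$intensity <- as.vector(unclass(kymo)[cbind(df$frame, df$bin)])
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin - 1) * bin,
                                   y = (.data$frame - 1) * dt,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "position (µm)", y = "time (s)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trajectory plot of linked tracks
#'
#' @param object An `axq_tracks` tibble from [detect_and_link()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot axq_tracks
#' @export
autoplot.axq_tracks <- function(object, ...) {
  dt <- attr(object, "frame_interval") %||% 0.2
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$position_um,
                               y = (.data$frame - 1) * dt,
                               group = .data$track,
                               colour = factor(.data$track))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (µm)", y = "time (s)") +
    ggplot2::theme_minimal()
}

#' Zone partition overview plot
#'
#' Terminal outline, active zone and the clipped 40-nm bands, with vesicle
#' centroids coloured by their assigned zone when `assignments` is given.
#'
#' @param partition An `axq_zone_partition`.
#' @param geometry The matching `axq_synapse_geometry`.
#' @param assignments Optional output of [assign_vesicles()].
#' @return A ggplot object.
#' @export
plot_zones <- function(partition, geometry, assignments = NULL) {
  ring_df <- purrr::imap_dfr(partition$polygons, function(rings, k) {
    purrr::imap_dfr(rings, function(r, j)
      tibble::tibble(zone = paste0("zone", k), ring = paste(k, j),
                     x = r$x, y = r$y))
  })
  term <- tibble::as_tibble(as.data.frame(geometry$terminal))
  names(term) <- c("x", "y")
  az <- tibble::as_tibble(as.data.frame(geometry$active_zone))
  names(az) <- c("x", "y")
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = ring_df,
                          ggplot2::aes(.data$x, .data$y, group = .data$ring,
                                       fill = .data$zone), alpha = 0.4) +
    ggplot2::geom_polygon(data = term, ggplot2::aes(.data$x, .data$y),
                          fill = NA, colour = "black") +
    ggplot2::geom_path(data = az, ggplot2::aes(.data$x, .data$y),
                       colour = "red", linewidth = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  if (!is.null(assignments))
    p <- p + ggplot2::geom_point(
      data = assignments,
      ggplot2::aes(.data$x, .data$y, colour = .data$zone), size = 1.5)
  p
}

#' Paired-pulse ratio versus interstimulus interval
#'
#' @param object A tibble binding one or more `axq_ppr` rows (e.g. over
#'   several ISIs).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot axq_ppr
#' @export
autoplot.axq_ppr <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$isi_ms,
                               y = .data$ppr_mean_of_ratios)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "interstimulus interval (ms)",
                  y = "paired-pulse ratio") +
    ggplot2::theme_minimal()
}
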