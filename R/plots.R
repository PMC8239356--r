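#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an event catalogue as an xy map
#'
#' Each detected event is drawn at its xy centroid, sized by volume and
#' coloured by onset frame — a quick spatial overview of where and when the
#' network fired.
#'
#' @param object A `wave_events` catalogue.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wave_events <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(
    x = .data$centroid_x, y = .data$centroid_y,
    size = .data$volume, colour = .data$t_onset
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "onset (frame)") +
    ggplot2::scale_size_area(name = "volume (voxels)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (px)", y = "y (px)",
      title = sprintf("%d calcium events", nrow(ev))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a motion-correction trace
#'
#' @param object A `wave_motion` result from [correct_motion()].
#' @param ... Unused.
#' @return A ggplot object showing the estimated per-frame (dy, dx) shifts.
#' @export
autoplot.wave_motion <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("dy", "dx"),
    names_to = "axis", values_to = "shift_px"
  )
  ggplot2::ggplot(tr, ggplot2::aes(.data$frame, .data$shift_px, colour = .data$axis)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "frame", y = "estimated shift (px)") +
    ggplot2::theme_minimal()
}

#' Maximum-intensity projection of the event mask over time
#'
#' Renders how often each pixel was part of a detected event — the event
#' footprint map of the recording.
#'
#' @param mask Logical 3D mask from [extract_events()].
#' @return A ggplot object.
#' @export
plot_mask_projection <- function(mask) {
  counts <- apply(mask, c(2L, 3L), sum)
  df <- tidyr::expand_grid(y = seq_len(nrow(counts)), x = seq_len(ncol(counts)))
  df$frames_active <- counts[cbind(df$y, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$frames_active)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "frames active") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
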