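#' Calcium event incidence
#'
#' Number of detected events per cell per minute of recording — the
#' network-level activity measure. The cell count is user-supplied (cells
#' are counted manually or by separate labelling; the pipeline itself never
#' segments cells).
#'
#' @param catalog A `wave_events` catalogue (post-cleanup).
#' @param n_cells Number of cells in the field of view, or `NULL`.
#' @param recording_minutes Recording length in minutes.
#' @return Events per cell per minute, or `NA` (with a warning) when
#'   `n_cells` is missing.
#' @export
incidence <- function(catalog, n_cells, recording_minutes) {
  stopifnot(inherits(catalog, "wave_events"), recording_minutes > 0)
  if (is.null(n_cells) || is.na(n_cells)) {
    warning("`n_cells` not supplied; incidence is reported as NA", call. = FALSE)
    return(NA_real_)
  }
  stopifnot(n_cells >= 1)
  nrow(catalog$events) / (n_cells * recording_minutes)
}

#' Intercellular propagation speeds
#'
#' For every unordered neighbour pair with distinct onsets, the speed is the
#' centre-to-centre xy distance divided by the onset time difference:
#' `(distance_px * pixel_size) / (|delta_onset| * frame_interval)` in um/s.
#' Simultaneous pairs (onset difference 0) carry no propagation information
#' and are excluded.
#'
#' @param neighbours Tibble from [find_neighbours()].
#' @param pixel_size Microns per pixel.
#' @param frame_interval Seconds per frame.
#' @return List with `speeds` (tibble: `event_id`, `neighbour_id`,
#'   `speed_um_s`, one row per unordered pair) and `median` (um/s; `NA`
#'   when no pair qualifies).
#' @export
propagation_speeds <- function(neighbours, pixel_size = 0.586, frame_interval = 0.2) {
  stopifnot(frame_interval > 0, pixel_size > 0)
  pairs <- neighbours |>
    dplyr::mutate(
      .a = pmin(.data$event_id, .data$neighbour_id),
      .b = pmax(.data$event_id, .data$neighbour_id)
    ) |>
    dplyr::distinct(.data$.a, .data$.b, .keep_all = TRUE) |>
    dplyr::filter(abs(.data$delta_onset_frames) >= 1L) |>
    dplyr::mutate(
      speed_um_s = (.data$centre_distance_xy_px * pixel_size) /
        (abs(.data$delta_onset_frames) * frame_interval)
    ) |>
    dplyr::select(event_id = ".a", neighbour_id = ".b", "speed_um_s")
  list(
    speeds = pairs,
    median = if (nrow(pairs) > 0L) stats::median(pairs$speed_um_s) else NA_real_
  )
}

#' Per-event duration and distance travelled
#'
#' Duration is the temporal extent times the frame interval; distance
#' travelled is the diagonal of the xy bounding box times the pixel size
#' (a single-voxel event, extent 1 x 1, travels `sqrt(2) * pixel_size`).
#'
#' @param catalog A `wave_events` catalogue.
#' @param pixel_size Microns per pixel.
#' @param frame_interval Seconds per frame.
#' @return Tibble: `id`, `duration_s`, `distance_um`.
#' @export
durations_and_distances <- function(catalog, pixel_size = 0.586, frame_interval = 0.2) {
  stopifnot(inherits(catalog, "wave_events"))
  catalog$events |>
    dplyr::transmute(
      id = .data$id,
      duration_s = .data$extent_t * frame_interval,
      distance_um = sqrt(.data$extent_x^2 + .data$extent_y^2) * pixel_size
    )
}

#' Consequent neighbouring waves per event
#'
#' For every event, the number of distinct neighbours with strictly later
#' onset — the waves the event may have induced in its neighbourhood.
#' Simultaneous neighbours contribute to neither member of the pair.
#'
#' @param neighbours Tibble from [find_neighbours()].
#' @param catalog A `wave_events` catalogue.
#' @return List with `counts` (tibble: `event_id`, `n_consequent`) covering
#'   every event, and `mean`.
#' @export
neighbour_counts <- function(neighbours, catalog) {
  stopifnot(inherits(catalog, "wave_events"))
  later <- neighbours |>
    dplyr::filter(.data$delta_onset_frames > 0L) |>
    dplyr::distinct(.data$event_id, .data$neighbour_id) |>
    dplyr::count(.data$event_id, name = "n_consequent")
  counts <- tibble::tibble(event_id = catalog$events$id) |>
    dplyr::left_join(later, by = "event_id") |>
    dplyr::mutate(n_consequent = dplyr::coalesce(.data$n_consequent, 0L))
  list(
    counts = counts,
    mean = if (nrow(counts) > 0L) mean(counts$n_consequent) else 0
  )
}

#' Recording-level summary statistics
#'
#' The per-recording metrics used for group comparisons: incidence
#' (events/cell/min), median intercellular propagation speed (um/s), median
#' event duration (s), median distance travelled (um) and the mean number
#' of consequent neighbouring waves. Medians over empty sets are `NA`.
#' Group-comparison hypothesis testing is intentionally left to external
#' tooling; this table is the export for it.
#'
#' @param catalog A `wave_events` catalogue (post-cleanup).
#' @param neighbours Tibble from [find_neighbours()].
#' @param n_cells Cell count, or `NULL` (incidence becomes `NA`).
#' @param recording_minutes Recording length in minutes.
#' @param pixel_size Microns per pixel.
#' @param frame_interval Seconds per frame.
#' @return A one-row tibble of class `wave_summary`: `n_events`,
#'   `n_neighbour_pairs`, `incidence_per_cell_min`,
#'   `median_speed_um_s`, `median_duration_s`, `median_distance_um`,
#'   `mean_neighbour_count`.
#' @export
summarise_recording <- function(catalog, neighbours,
                                n_cells = NULL,
                                recording_minutes = 3,
                                pixel_size = 0.586,
                                frame_interval = 0.2) {
  sp <- propagation_speeds(neighbours, pixel_size, frame_interval)
  dd <- durations_and_distances(catalog, pixel_size, frame_interval)
  nc <- neighbour_counts(neighbours, catalog)
  inc <- if (is.null(n_cells)) {
    NA_real_
  } else {
    incidence(catalog, n_cells, recording_minutes)
  }
  out <- tibble::tibble(
    n_events = nrow(catalog$events),
    n_neighbour_pairs = nrow(sp$speeds),
    incidence_per_cell_min = inc,
    median_speed_um_s = sp$median,
    median_duration_s = if (nrow(dd) > 0L) stats::median(dd$duration_s) else NA_real_,
    median_distance_um = if (nrow(dd) > 0L) stats::median(dd$distance_um) else NA_real_,
    mean_neighbour_count = nc$mean
  )
  class(out) <- c("wave_summary", class(out))
  out
}

#' Glance method for a recording summary
#'
#' @param x A `wave_summary` tibble.
#' @param ... Unused.
#' @return `x` as a plain tibble (already one row).
#' @export
glance.wave_summary <- function(x, ...) tibble::as_tibble(unclass(x))
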