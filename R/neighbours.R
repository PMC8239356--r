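#' Find neighbouring calcium events
#'
#' Around every event a boundary box is placed, centred at the event's
#' centroid; its half-width along each axis is the maximum distance from the
#' centroid to the event's extreme foreground voxel on that axis, padded by
#' `tolerance_xy` (x and y) or `tolerance_t` (t). Any other event with at
#' least one voxel inside the box (boundaries inclusive) is recorded as a
#' neighbour. Both directions are evaluated independently, so one ordered
#' record per qualifying (event, neighbour) pair is returned.
#'
#' @param catalog A `wave_events` catalogue from [catalog_events()].
#' @param tolerance_xy Box padding in pixels (default 50).
#' @param tolerance_t Box padding in frames (default 5).
#' @return Tibble with one row per ordered neighbour pair: `event_id`,
#'   `neighbour_id`, `centre_distance_xy_px`, `delta_onset_frames`
#'   (neighbour onset minus event onset), `neighbour_extent_x`,
#'   `neighbour_extent_y`, `neighbour_extent_t`.
#' @export
find_neighbours <- function(catalog, tolerance_xy = 50, tolerance_t = 5L) {
  stopifnot(inherits(catalog, "wave_events"))
  ev <- catalog$events
  k <- nrow(ev)
  empty <- tibble::tibble(
    event_id = integer(), neighbour_id = integer(),
    centre_distance_xy_px = double(), delta_onset_frames = integer(),
    neighbour_extent_x = integer(), neighbour_extent_y = integer(),
    neighbour_extent_t = integer()
  )
  if (k < 2L) {
    return(empty)
  }
  # 0-based voxel coordinates per event
  vox0 <- lapply(catalog$voxels, function(v) v[, c("t", "y", "x"), drop = FALSE] - 1L)
  half <- matrix(0, k, 3L) # half-widths (t, y, x) before padding
  for (i in seq_len(k)) {
    cen <- c(ev$centroid_t[i], ev$centroid_y[i], ev$centroid_x[i])
    half[i, ] <- apply(abs(sweep(vox0[[i]], 2L, cen)), 2L, max)
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    cen <- c(ev$centroid_t[i], ev$centroid_y[i], ev$centroid_x[i])
    lim <- half[i, ] + c(tolerance_t, tolerance_xy, tolerance_xy)
    hits <- integer(0)
    for (j in seq_len(k)) {
      if (j == i) next
      d <- abs(sweep(vox0[[j]], 2L, cen))
      if (any(d[, 1L] <= lim[1L] & d[, 2L] <= lim[2L] & d[, 3L] <= lim[3L])) {
        hits <- c(hits, j)
      }
    }
    if (length(hits) > 0L) {
      out[[i]] <- tibble::tibble(
        event_id = ev$id[i],
        neighbour_id = ev$id[hits],
        centre_distance_xy_px = catalog$centre_distances[i, hits],
        delta_onset_frames = ev$t_onset[hits] - ev$t_onset[i],
        neighbour_extent_x = ev$extent_x[hits],
        neighbour_extent_y = ev$extent_y[hits],
        neighbour_extent_t = ev$extent_t[hits]
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty else res
}

# overlap fraction of two xy footprints: |A n B| / min(|A|, |B|)
.overlap_fraction <- function(pa, pb) {
  ka <- paste(pa[, 1L], pa[, 2L])
  kb <- paste(pb[, 1L], pb[, 2L])
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Classify events as single or repeated firing of one site
#'
#' Two neighbouring events whose xy footprints overlap by strictly more than
#' `intersection_threshold` (fraction of the smaller footprint) are linked
#' as repeats — the same site firing again rather than propagation to a new
#' site. Chains of repeats are the connected components of the link graph;
#' every chain member is classified `"repeat"`, all other events
#' `"single"`. Inter-repeat gaps are the onset differences between
#' consecutive, time-ordered chain members.
#'
#' @param neighbours Tibble from [find_neighbours()].
#' @param catalog The `wave_events` catalogue.
#' @param intersection_threshold Strict overlap threshold in (0, 1],
#'   default 0.8.
#' @return An object of class `wave_repeats`: list with
#'   `classification` (tibble: `event_id`, `category`, `chain_id`) and
#'   `chains` (tibble: `chain_id`, `event_id`, `t_onset`,
#'   `gap_from_previous_frames`, ordered by onset within chain).
#' @export
find_repeats <- function(neighbours, catalog, intersection_threshold = 0.8) {
  stopifnot(inherits(catalog, "wave_events"))
  ev <- catalog$events
  pairs <- neighbours[neighbours$event_id < neighbours$neighbour_id, , drop = FALSE]
  linked <- matrix(integer(0), ncol = 2L)
  if (nrow(pairs) > 0L) {
    f <- vapply(
      seq_len(nrow(pairs)),
      function(r) {
        .overlap_fraction(
          catalog$projections[[pairs$event_id[r]]],
          catalog$projections[[pairs$neighbour_id[r]]]
        )
      },
      double(1)
    )
    linked <- cbind(pairs$event_id[f > intersection_threshold],
      pairs$neighbour_id[f > intersection_threshold])
  }
  chain_id <- rep(NA_integer_, nrow(ev))
  if (nrow(linked) > 0L) {
    g <- igraph::graph_from_edgelist(matrix(as.character(linked), ncol = 2L),
      directed = FALSE
    )
    comp <- igraph::components(g)
    member_ids <- as.integer(igraph::V(g)$name)
    # number chains by their earliest member id, for reproducibility
    first_member <- vapply(
      seq_len(comp$no),
      function(cc) min(member_ids[comp$membership == cc]), integer(1)
    )
    renum <- rank(first_member)[comp$membership]
    chain_id[member_ids] <- as.integer(renum)
  }
  classification <- tibble::tibble(
    event_id = ev$id,
    category = ifelse(is.na(chain_id), "single", "repeat"),
    chain_id = chain_id
  )
  chains <- classification |>
    dplyr::filter(!is.na(.data$chain_id)) |>
    dplyr::left_join(ev[, c("id", "t_onset")], by = c(event_id = "id")) |>
    dplyr::arrange(.data$chain_id, .data$t_onset, .data$event_id) |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::mutate(gap_from_previous_frames = .data$t_onset - dplyr::lag(.data$t_onset)) |>
    dplyr::ungroup() |>
    dplyr::select("chain_id", "event_id", "t_onset", "gap_from_previous_frames")
  structure(
    list(classification = classification, chains = chains),
    class = "wave_repeats"
  )
}

#' @export
print.wave_repeats <- function(x, ...) {
  cat(sprintf(
    "<wave_repeats> %d events: %d repeat (in %d chains), %d single\n",
    nrow(x$classification),
    sum(x$classification$category == "repeat"),
    length(unique(stats::na.omit(x$classification$chain_id))),
    sum(x$classification$category == "single")
  ))
  invisible(x)
}

#' Tidy a repeat classification
#'
#' @param x A `wave_repeats` object.
#' @param ... Unused.
#' @return The per-event classification tibble.
#' @export
tidy.wave_repeats <- function(x, ...) x$classification

#' Write the neighbourhood CSV outputs
#'
#' Writes four RFC-4180 CSV files ("." decimal separator, header row, one
#' per output table): `neighbours.csv` (one row per ordered neighbour
#' record), `neighbour_statistics.csv` (per-event neighbour count, mean
#' centre distance and mean |delta onset|, plus one `ALL` row of
#' recording-level means), `repeats.csv` (chain membership, dimensions and
#' inter-repeat gaps) and `singles.csv` (dimensions of single events).
#' Empty inputs produce header-only files.
#'
#' @param neighbours Tibble from [find_neighbours()].
#' @param repeats A `wave_repeats` object from [find_repeats()].
#' @param catalog The `wave_events` catalogue.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written file paths, invisibly.
#' @export
generate_csv <- function(neighbours, repeats, catalog, out_dir) {
  stopifnot(inherits(catalog, "wave_events"), inherits(repeats, "wave_repeats"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ev <- catalog$events
  paths <- c(
    neighbours = file.path(out_dir, "neighbours.csv"),
    neighbour_statistics = file.path(out_dir, "neighbour_statistics.csv"),
    repeats = file.path(out_dir, "repeats.csv"),
    singles = file.path(out_dir, "singles.csv")
  )
  utils::write.csv(neighbours, paths[["neighbours"]], row.names = FALSE)

  if (nrow(neighbours) > 0L) {
    per_event <- neighbours |>
      dplyr::group_by(event_id = .data$event_id) |>
      dplyr::summarise(
        n_neighbours = dplyr::n(),
        mean_centre_distance_xy_px = mean(.data$centre_distance_xy_px),
        mean_abs_delta_onset_frames = mean(abs(.data$delta_onset_frames))
      )
    overall <- tibble::tibble(
      event_id = NA_integer_,
      n_neighbours = mean(per_event$n_neighbours),
      mean_centre_distance_xy_px = mean(per_event$mean_centre_distance_xy_px),
      mean_abs_delta_onset_frames = mean(per_event$mean_abs_delta_onset_frames)
    )
    stats_tbl <- dplyr::bind_rows(
      per_event,
      dplyr::mutate(overall, event_id = NA_integer_)
    )
    stats_tbl$event_id <- c(as.character(per_event$event_id), "ALL")
  } else {
    stats_tbl <- tibble::tibble(
      event_id = character(), n_neighbours = double(),
      mean_centre_distance_xy_px = double(),
      mean_abs_delta_onset_frames = double()
    )
  }
  utils::write.csv(stats_tbl, paths[["neighbour_statistics"]], row.names = FALSE)

  dims <- ev[, c("id", "volume", "t_onset", "t_end", "extent_x", "extent_y", "extent_t")]
  rep_tbl <- repeats$chains |>
    dplyr::left_join(dims[, setdiff(names(dims), "t_onset")], by = c(event_id = "id")) |>
    dplyr::select(
      "chain_id", "event_id", "t_onset", "gap_from_previous_frames",
      "volume", "extent_x", "extent_y", "extent_t"
    )
  utils::write.csv(rep_tbl, paths[["repeats"]], row.names = FALSE)

  singles_ids <- repeats$classification$event_id[repeats$classification$category == "single"]
  utils::write.csv(dims[dims$id %in% singles_ids, , drop = FALSE],
    paths[["singles"]],
    row.names = FALSE
  )
  invisible(paths)
}
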