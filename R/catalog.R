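#' List the voxel coordinates of every labelled event
#'
#' @param labels Integer 3D label array from [create_masks()] / [cleanup()].
#' @return A list of integer matrices, one per event ID, each with columns
#'   `t`, `y`, `x` (1-based array coordinates), rows sorted
#'   lexicographically by (t, y, x). Every foreground voxel appears in
#'   exactly one matrix.
#' @export
label_events <- function(labels) {
  k <- max(labels)
  if (k == 0L) {
    return(list())
  }
  idx <- which(labels > 0L)
  ai <- arrayInd(idx, dim(labels))
  colnames(ai) <- c("t", "y", "x")
  lb <- labels[idx]
  ord <- order(lb, ai[, 1L], ai[, 2L], ai[, 3L])
  ai <- ai[ord, , drop = FALSE]
  lb <- lb[ord]
  grp <- split(seq_len(nrow(ai)), factor(lb, levels = seq_len(k)))
  unname(lapply(grp, function(rows) ai[rows, , drop = FALSE]))
}

#' Build the event catalogue
#'
#' For every event: volume, onset/end frames, axis-aligned bounding-box
#' extents in x, y (pixels) and t (frames, voxel-count convention: a
#' single-voxel event has extent 1 on every axis), the intensity-weighted
#' centre of mass over its voxels, and the xy footprint (projection). The
#' catalogue also carries the full matrix of pairwise xy Euclidean distances
#' between event centroids — the raw material of the intercellular
#' propagation analysis. Events whose total intensity is zero fall back to
#' the unweighted voxel mean and are flagged in `centroid_unweighted`.
#'
#' All coordinates in the returned table are 0-based (frame 0, pixel 0),
#' matching the frame/pixel units used throughout.
#'
#' @param voxel_lists Output of [label_events()].
#' @param intensities The [image_stack()] detection ran on (pre-processed if
#'   pre-processing was applied).
#' @return An object of class `wave_events`: list with
#'   \describe{
#'     \item{events}{tibble: `id`, `volume`, `t_onset`, `t_end`, `extent_x`,
#'       `extent_y`, `extent_t`, `centroid_t`, `centroid_y`, `centroid_x`,
#'       `centroid_unweighted`.}
#'     \item{centre_distances}{K x K symmetric matrix of xy centroid
#'       distances in pixels.}
#'     \item{projections}{list of integer matrices (`y`, `x`), the unique
#'       xy footprint of each event.}
#'     \item{voxels}{the input voxel lists, with per-voxel intensity.}
#'   }
#' @export
generate_metadata <- function(voxel_lists, intensities) {
  stopifnot(inherits(intensities, "wave_stack"))
  k <- length(voxel_lists)
  if (k == 0L) {
    return(structure(
      list(
        events = tibble::tibble(
          id = integer(), volume = integer(), t_onset = integer(),
          t_end = integer(), extent_x = integer(), extent_y = integer(),
          extent_t = integer(), centroid_t = double(), centroid_y = double(),
          centroid_x = double(), centroid_unweighted = logical()
        ),
        centre_distances = matrix(0, 0, 0),
        projections = list(),
        voxels = list()
      ),
      class = "wave_events"
    ))
  }
  dm <- dim(intensities$data)
  rows <- vector("list", k)
  projections <- vector("list", k)
  voxels <- vector("list", k)
  for (i in seq_len(k)) {
    vx <- voxel_lists[[i]]
    inten <- intensities$data[.lin3(vx[, 1L], vx[, 2L], vx[, 3L], dm)]
    tot <- sum(inten)
    unweighted <- tot <= 0
    wts <- if (unweighted) rep(1, nrow(vx)) else inten
    cen <- colSums(vx * wts) / sum(wts) # 1-based (t, y, x)
    proj <- unique(vx[, c("y", "x"), drop = FALSE])
    rows[[i]] <- tibble::tibble(
      id = i,
      volume = nrow(vx),
      t_onset = min(vx[, "t"]) - 1L,
      t_end = max(vx[, "t"]) - 1L,
      extent_x = diff(range(vx[, "x"])) + 1L,
      extent_y = diff(range(vx[, "y"])) + 1L,
      extent_t = diff(range(vx[, "t"])) + 1L,
      centroid_t = cen[["t"]] - 1,
      centroid_y = cen[["y"]] - 1,
      centroid_x = cen[["x"]] - 1,
      centroid_unweighted = unweighted
    )
    projections[[i]] <- proj
    voxels[[i]] <- cbind(vx, intensity = inten)
  }
  events <- dplyr::bind_rows(rows)
  cd <- as.matrix(stats::dist(cbind(events$centroid_x, events$centroid_y)))
  dimnames(cd) <- list(events$id, events$id)
  structure(
    list(
      events = events, centre_distances = cd,
      projections = projections, voxels = voxels
    ),
    class = "wave_events"
  )
}

#' Run labelling + cataloguing in one call
#'
#' Convenience wrapper: [label_events()] then [generate_metadata()].
#'
#' @inheritParams label_events
#' @inheritParams generate_metadata
#' @return A `wave_events` catalogue.
#' @export
catalog_events <- function(labels, intensities) {
  generate_metadata(label_events(labels), intensities)
}

#' @export
print.wave_events <- function(x, ...) {
  cat(sprintf("<wave_events> %d calcium events\n", nrow(x$events)))
  if (nrow(x$events) > 0) print(x$events, n = 5)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an event catalogue into one row per event
#'
#' @param x A `wave_events` object.
#' @param ... Unused.
#' @return The per-event tibble.
#' @export
tidy.wave_events <- function(x, ...) x$events

#' One-row overview of an event catalogue
#'
#' @param x A `wave_events` object.
#' @param ... Unused.
#' @return Tibble with `n_events`, `total_volume`, `median_volume`,
#'   `median_extent_t`.
#' @export
glance.wave_events <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$events),
    total_volume = sum(x$events$volume),
    median_volume = if (nrow(x$events)) stats::median(x$events$volume) else NA_real_,
    median_extent_t = if (nrow(x$events)) stats::median(x$events$extent_t) else NA_real_
  )
}
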