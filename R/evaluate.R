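#' Match detected events against planted ground truth
#'
#' Greedy one-to-one matching: truth events are paired with the closest
#' detected centroid (xy distance) among detections whose centroid lies
#' within `max_dist_px` and whose onset is within `max_dt_frames`, closest
#' pairs first. From the matching, detector recall and precision, the onset
#' error (detected first frame minus planted onset) and the xy centroid
#' error are computed.
#'
#' @param truth Ground-truth tibble from [generate_stack()].
#' @param catalog A `wave_events` catalogue of the detections.
#' @param max_dist_px Match gate on the xy centroid distance.
#' @param max_dt_frames Match gate on the onset difference.
#' @return List: `matches` (tibble `event`, `id`, `onset_error_frames`,
#'   `centroid_error_px`), `recall`, `precision`, `mean_onset_error`,
#'   `mean_centroid_error` (means of absolute errors over matches; `NA`
#'   when nothing matches).
#' @export
evaluate_detection <- function(truth, catalog, max_dist_px = 10, max_dt_frames = 5) {
  stopifnot(inherits(catalog, "wave_events"))
  ev <- catalog$events
  if (nrow(truth) == 0L || nrow(ev) == 0L) {
    return(list(
      matches = tibble::tibble(
        event = integer(), id = integer(),
        onset_error_frames = double(), centroid_error_px = double()
      ),
      recall = if (nrow(truth) == 0L) NA_real_ else 0,
      precision = if (nrow(ev) == 0L) NA_real_ else 0,
      mean_onset_error = NA_real_, mean_centroid_error = NA_real_
    ))
  }
  d_xy <- outer(truth$y, ev$centroid_y, "-")^2 + outer(truth$x, ev$centroid_x, "-")^2
  d_xy <- sqrt(d_xy)
  d_t <- abs(outer(truth$onset, ev$t_onset, "-"))
  d_xy[d_xy > max_dist_px | d_t > max_dt_frames] <- Inf
  matches <- list()
  used_t <- logical(nrow(truth))
  used_d <- logical(nrow(ev))
  repeat {
    m <- which.min(d_xy)
    if (length(m) == 0L || !is.finite(d_xy[m])) break
    ij <- arrayInd(m, dim(d_xy))
    i <- ij[1L]
    j <- ij[2L]
    matches[[length(matches) + 1L]] <- tibble::tibble(
      event = truth$event[i], id = ev$id[j],
      onset_error_frames = ev$t_onset[j] - truth$onset[i],
      centroid_error_px = d_xy[m]
    )
    used_t[i] <- TRUE
    used_d[j] <- TRUE
    d_xy[i, ] <- Inf
    d_xy[, j] <- Inf
  }
  matches <- if (length(matches)) dplyr::bind_rows(matches) else tibble::tibble(
    event = integer(), id = integer(),
    onset_error_frames = double(), centroid_error_px = double()
  )
  list(
    matches = matches,
    recall = sum(used_t) / nrow(truth),
    precision = sum(used_d) / nrow(ev),
    mean_onset_error = if (nrow(matches)) mean(abs(matches$onset_error_frames)) else NA_real_,
    mean_centroid_error = if (nrow(matches)) mean(matches$centroid_error_px) else NA_real_
  )
}
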