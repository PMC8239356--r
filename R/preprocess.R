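#' Frame-mean intensity correction
#'
#' Removes slow global intensity drift (typically photobleaching) by
#' matching the mean intensity of every frame to the mean of the preceding
#' frame. Cascading that matching through the recording is equivalent to
#' rescaling every frame to the first frame's mean, which is how it is
#' implemented: each frame is multiplied by `mean(frame 1) / mean(frame t)`.
#' The spatial pattern of every frame (frame divided by its own mean) is
#' unchanged.
#'
#' @param stack A [image_stack()] object; every frame must have positive mean.
#' @return A corrected `wave_stack` whose frame means are all equal to the
#'   first frame's mean (relative tolerance ~1e-9).
#' @export
correct_intensity <- function(stack) {
  stopifnot(inherits(stack, "wave_stack"))
  m <- apply(stack$data, 1L, mean)
  if (any(m <= 0)) {
    stop("degenerate input: a frame has non-positive mean intensity", call. = FALSE)
  }
  out <- stack$data * (m[1L] / m) # recycles along the first (frame) axis
  image_stack(out,
    frame_interval = stack$frame_interval,
    pixel_size = stack$pixel_size
  )
}

# subregion index grid: frames divided into grid x grid tiles, numbered
# row-major (1 = top-left). Returns per-pixel tile id (height x width).
.subregion_ids <- function(height, width, grid) {
  ry <- pmin(ceiling(seq_len(height) / (height / grid)), grid)
  rx <- pmin(ceiling(seq_len(width) / (width / grid)), grid)
  outer(ry, rx, function(a, b) (a - 1L) * grid + b)
}

#' Select motion-correction reference subregions
#'
#' Divides the field of view into a `grid` x `grid` tiling and selects the
#' tiles whose temporal trace has below-median SD and above-median mean:
#' bright, quiet regions that carry no calcium transients and can anchor
#' rigid registration. If that intersection is empty every tile is scored by
#' `mean / (SD + eps)` and the single best (lowest index on ties) is used.
#'
#' @param stack A [image_stack()] object.
#' @param grid Tiles per axis; the frame must be at least `grid` pixels in
#'   each dimension and the tiling must produce at least 4 tiles.
#' @return An object of class `wave_reference`: list with `tiles` (integer
#'   ids), `grid`, and the pixel bounding box (`rows`, `cols`) of the
#'   selected tile set.
#' @export
select_reference <- function(stack, grid = 8L) {
  stopifnot(inherits(stack, "wave_stack"))
  grid <- as.integer(grid)
  if (grid * grid < 4L) stop("grid must yield at least 4 subregions", call. = FALSE)
  if (stack$height < grid || stack$width < grid) {
    stop("frame too small for a ", grid, "x", grid, " subregion grid", call. = FALSE)
  }
  ids <- .subregion_ids(stack$height, stack$width, grid)
  n_tiles <- grid * grid
  # per-tile per-frame mean trace
  px <- matrix(stack$data, nrow = stack$n_frames) # columns = pixels, (y,x) col-major
  sums <- rowsum(t(px), as.vector(ids)) # tiles x frames
  counts <- tabulate(as.vector(ids), nbins = n_tiles)
  traces <- sums / counts
  tile_mean <- rowMeans(traces)
  tile_sd <- apply(traces, 1L, stats::sd)
  keep <- which(tile_sd < stats::median(tile_sd) & tile_mean > stats::median(tile_mean))
  if (length(keep) == 0L) {
    keep <- which.max(tile_mean / (tile_sd + 1e-12))
  }
  sel <- array(ids %in% keep, dim(ids))
  rows <- range(which(apply(sel, 1L, any)))
  cols <- range(which(apply(sel, 2L, any)))
  structure(
    list(tiles = unname(sort(keep)), grid = grid, rows = rows, cols = cols),
    class = "wave_reference"
  )
}

# circular 2D cross-correlation peak between two equal-size matrices,
# returning the integer shift (dy, dx) of `b` relative to `a`, folded into
# the signed range (-n/2, n/2].
.xcorr_shift <- function(a, b) {
  a <- a - mean(a)
  b <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  fold <- function(k, n) {
    s <- k - 1L
    if (s > n / 2) s - n else s
  }
  c(-fold(pk[1L], nrow(a)), -fold(pk[2L], ncol(a)))
}

# translate one frame by integer (dy, dx), zero-filling vacated margins
.translate_frame <- function(fr, dy, dx) {
  out <- matrix(0, nrow(fr), ncol(fr))
  ys <- max(1L, 1L + dy):min(nrow(fr), nrow(fr) + dy)
  xs <- max(1L, 1L + dx):min(ncol(fr), ncol(fr) + dx)
  if (length(ys) > 0L && length(xs) > 0L) {
    out[ys, xs] <- fr[ys - dy, xs - dx, drop = FALSE]
  }
  out
}

#' Rigid motion correction
#'
#' Estimates a per-frame integer (dy, dx) translation by locating the
#' cross-correlation peak between each frame's reference-region crop and the
#' first frame's crop, then shifts each frame back by that translation
#' (vacated margins zero-filled). Registration is always against frame 1,
#' not the preceding frame, so estimation errors cannot accumulate as drift.
#' A frame whose estimated shift exceeds half the frame size is flagged as a
#' failure and inherits the previous frame's shift.
#'
#' @param stack A [image_stack()] object.
#' @param reference A `wave_reference` from [select_reference()]; computed
#'   automatically when omitted.
#' @param grid Passed to [select_reference()] when `reference` is `NULL`.
#' @return A list with `stack` (the corrected `wave_stack`) and `trace`
#'   (a tibble: `frame`, `dy`, `dx`, `failed`), class `wave_motion`.
#' @export
correct_motion <- function(stack, reference = NULL, grid = 8L) {
  stopifnot(inherits(stack, "wave_stack"))
  if (is.null(reference)) reference <- select_reference(stack, grid = grid)
  stopifnot(inherits(reference, "wave_reference"))
  ys <- reference$rows[1L]:reference$rows[2L]
  xs <- reference$cols[1L]:reference$cols[2L]
  ref0 <- stack$data[1L, ys, xs, drop = TRUE]
  if (is.null(dim(ref0))) ref0 <- matrix(ref0, length(ys), length(xs))
  n <- stack$n_frames
  dy <- integer(n)
  dx <- integer(n)
  failed <- logical(n)
  out <- stack$data
  for (t in seq_len(n)[-1L]) {
    crop <- stack$data[t, ys, xs, drop = TRUE]
    if (is.null(dim(crop))) crop <- matrix(crop, length(ys), length(xs))
    sh <- .xcorr_shift(ref0, crop)
    if (abs(sh[1L]) > stack$height / 2 || abs(sh[2L]) > stack$width / 2) {
      failed[t] <- TRUE
      sh <- c(dy[t - 1L], dx[t - 1L])
    }
    dy[t] <- sh[1L]
    dx[t] <- sh[2L]
    if (dy[t] != 0L || dx[t] != 0L) {
      out[t, , ] <- .translate_frame(stack$data[t, , ], -dy[t], -dx[t])
    }
  }
  structure(
    list(
      stack = image_stack(out,
        frame_interval = stack$frame_interval,
        pixel_size = stack$pixel_size
      ),
      trace = tibble::tibble(
        frame = seq_len(n) - 1L, dy = dy, dx = dx, failed = failed
      ),
      reference = reference
    ),
    class = "wave_motion"
  )
}

#' @export
print.wave_motion <- function(x, ...) {
  moved <- sum(x$trace$dy != 0 | x$trace$dx != 0)
  cat(sprintf(
    "<wave_motion> %d frames, %d shifted, max |shift| = %d px\n",
    nrow(x$trace), moved, max(abs(c(x$trace$dy, x$trace$dx)))
  ))
  invisible(x)
}
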