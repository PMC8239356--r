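#' Construct an image stack
#'
#' The central raster container of the pipeline: a 3D intensity volume
#' indexed `(frame, row, column)` together with the acquisition calibration
#' needed to convert pixels and frames into microns and seconds. All
#' geometry inside the pipeline stays in pixel/frame units; physical units
#' are applied only by the summary functions.
#'
#' @param data Numeric 3D array indexed `(frame, row, column)`; all values
#'   must be finite and non-negative, with at least two frames.
#' @param frame_interval Seconds per frame (default 0.2, i.e. 5 frames/s).
#' @param pixel_size Microns per pixel (default 0.586).
#'
#' @return An object of class `wave_stack`: a list with elements `data`,
#'   `n_frames`, `height`, `width`, `frame_interval`, `pixel_size`.
#' @examples
#' st <- image_stack(array(runif(2 * 4 * 4), dim = c(2, 4, 4)))
#' st$n_frames
#' @export
image_stack <- function(data, frame_interval = 0.2, pixel_size = 0.586) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array indexed (frame, row, column)", call. = FALSE)
  }
  if (dim(data)[1L] < 2L) {
    stop("degenerate input: a stack needs at least 2 frames", call. = FALSE)
  }
  if (!all(is.finite(data)) || any(data < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  stopifnot(frame_interval > 0, pixel_size > 0)
  structure(
    list(
      data = data,
      n_frames = dim(data)[1L],
      height = dim(data)[2L],
      width = dim(data)[3L],
      frame_interval = frame_interval,
      pixel_size = pixel_size
    ),
    class = "wave_stack"
  )
}

#' @export
print.wave_stack <- function(x, ...) {
  cat(sprintf(
    "<wave_stack> %d frames of %d x %d px (%.3g s/frame, %.3g um/px)\n",
    x$n_frames, x$height, x$width, x$frame_interval, x$pixel_size
  ))
  invisible(x)
}

#' @export
dim.wave_stack <- function(x) dim(x$data)

#' Read a multi-page grayscale TIFF time-lapse
#'
#' Reads every page of a TIFF file into an image stack, one page per frame,
#' in file order. Integer intensities are preserved bit-exactly (no
#' rescaling); floating-point TIFFs are read as stored. Colour or
#' multi-channel files are rejected: the pipeline operates on single-channel
#' fluorescence recordings.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @inheritParams image_stack
#' @return A [image_stack()] object.
#' @seealso [write_stack()] for the inverse operation.
#' @export
read_stack <- function(path, frame_interval = 0.2, pixel_size = 0.586) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    stop("degenerate input: TIFF has fewer than 2 frames", call. = FALSE)
  }
  for (p in pages) {
    if (length(dim(p)) > 2L && dim(p)[3L] > 1L) {
      stop("unsupported format: multi-channel (RGB) TIFF; a grayscale stack is required",
        call. = FALSE
      )
    }
  }
  h <- nrow(pages[[1L]])
  w <- ncol(pages[[1L]])
  data <- array(0, dim = c(length(pages), h, w))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    if (nrow(p) != h || ncol(p) != w) {
      stop("all TIFF pages must share one frame size", call. = FALSE)
    }
    data[i, , ] <- p
  }
  image_stack(data, frame_interval = frame_interval, pixel_size = pixel_size)
}

#' Write an image stack as a multi-page TIFF
#'
#' Integer-valued stacks round-trip bit-exactly through
#' [read_stack()] at the chosen bit depth.
#'
#' @param stack A [image_stack()] object.
#' @param path Output file path.
#' @param bits_per_sample 8 or 16; values must lie in `[0, 2^bits - 1]`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(inherits(stack, "wave_stack"), bits_per_sample %in% c(8L, 16L))
  top <- 2^bits_per_sample - 1
  if (max(stack$data) > top) {
    stop("intensities exceed the requested bit depth", call. = FALSE)
  }
  pages <- lapply(seq_len(stack$n_frames), function(t) stack$data[t, , ] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

# ---- minimal NPY v1.0 serialisation ----------------------------------------
# The pipeline's array artifacts keep their customary filenames (waves.npy,
# labelled_waves.npy); NPY v1.0 is a trivial header + raw little-endian
# buffer, written in C (row-major) order.

npy_dtype <- function(dtype) {
  switch(dtype,
    uint8 = list(descr = "|u1", size = 1L, what = "integer"),
    int32 = list(descr = "<i4", size = 4L, what = "integer"),
    float64 = list(descr = "<f8", size = 8L, what = "double"),
    stop("unsupported NPY dtype: ", dtype, call. = FALSE)
  )
}

#' Write an array in NPY format
#'
#' @param a Integer or numeric array (any number of dimensions).
#' @param path Output path.
#' @param dtype One of `"uint8"`, `"int32"`, `"float64"`.
#' @return `path`, invisibly.
#' @keywords internal
#' @export
write_npy <- function(a, path, dtype = "int32") {
  dt <- npy_dtype(dtype)
  dims <- dim(a)
  if (is.null(dims)) dims <- length(a)
  shape <- paste0("(", paste0(dims, ",", collapse = " "), ")")
  shape <- sub(", \\)$", ")", sub(",\\)$", ",)", shape))
  header <- sprintf(
    "{'descr': '%s', 'fortran_order': False, 'shape': %s, }", dt$descr, shape
  )
  # pad so that 10 + header length is a multiple of 64, terminated by \n
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  flat <- if (length(dims) > 1L) as.vector(aperm(a, rev(seq_along(dims)))) else as.vector(a)
  if (dt$what == "integer") flat <- as.integer(flat) else flat <- as.double(flat)
  writeBin(flat, con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read an NPY array written by [write_npy()]
#'
#' Supports the uint8 / int32 / float64 C-order subset this package emits.
#'
#' @param path Path to a `.npy` file.
#' @return An array with the stored shape.
#' @keywords internal
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], as.raw(c(0x93, utf8ToInt("NUMPY"))))) {
    stop("not an NPY file: ", path, call. = FALSE)
  }
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr': '([^']+)'.*", "\\1", header)
  shape_s <- sub(".*'shape': \\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("[ ]", "", shape_s), ",")[[1]])
  if (grepl("'fortran_order': True", header)) {
    stop("fortran-order NPY not supported", call. = FALSE)
  }
  n <- prod(dims)
  flat <- switch(descr,
    "|u1" = readBin(con, "integer", n, size = 1L, signed = FALSE),
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    stop("unsupported NPY dtype: ", descr, call. = FALSE)
  )
  if (length(dims) > 1L) {
    aperm(array(flat, dim = rev(dims)), rev(seq_along(dims)))
  } else {
    flat
  }
}
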