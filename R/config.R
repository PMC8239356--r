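#' Pipeline configuration
#'
#' Holds every user-tunable parameter of the pipeline plus the physical
#' calibration of the recording. Defaults are the values used for the
#' reference astrocytic-culture recordings.
#'
#' @param filename Input selector: a file name, or `"All"` to process every
#'   TIFF in the input directory (lexicographic order).
#' @param intersection_threshold Fraction in `(0, 1]`: two neighbouring
#'   events whose xy footprints overlap by *more than* this fraction (of the
#'   smaller footprint) are classified as repeated firing of one site.
#' @param grain_size Side, in pixels, of the square pixel blocks whose
#'   temporal traces drive detection; must be a power of two.
#' @param sd_threshold Positive multiplier `k`: a grain is foreground at
#'   frame `t` when its block-mean intensity reaches `mu + k * sigma` of its
#'   full temporal trace.
#' @param tolerance_t Maximum frame distance for two events to count as
#'   neighbours (padding of the bounding box along t).
#' @param tolerance_xy Maximum xy pixel distance for neighbourhood (padding
#'   of the bounding box in x and y).
#' @param use_watershed Split touching events with a seeded 3D watershed?
#' @param volume_threshold Events with fewer voxels than this are discarded
#'   as noise (an event of exactly this volume is retained).
#' @param n_cells Optional astrocyte count in the field of view, required
#'   only for the incidence summary.
#' @param frame_interval,pixel_size Acquisition calibration, see
#'   [image_stack()].
#'
#' @return An object of class `wave_config` (a named list).
#' @examples
#' wave_config(sd_threshold = 2, grain_size = 4)
#' @export
wave_config <- function(filename = "All",
                        intersection_threshold = 0.8,
                        grain_size = 1L,
                        sd_threshold = 5,
                        tolerance_t = 5L,
                        tolerance_xy = 50,
                        use_watershed = FALSE,
                        volume_threshold = 40L,
                        n_cells = NULL,
                        frame_interval = 0.2,
                        pixel_size = 0.586) {
  grain_size <- as.integer(grain_size)
  if (grain_size < 1L || bitwAnd(grain_size, grain_size - 1L) != 0L) {
    stop("`grain_size` must be a power of two (1, 2, 4, 8, ...)", call. = FALSE)
  }
  if (!(intersection_threshold > 0 && intersection_threshold <= 1)) {
    stop("`intersection_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (sd_threshold <= 0) stop("`sd_threshold` must be positive", call. = FALSE)
  if (tolerance_t < 0 || tolerance_xy < 0) {
    stop("tolerances must be non-negative", call. = FALSE)
  }
  if (volume_threshold < 0) stop("`volume_threshold` must be >= 0", call. = FALSE)
  if (!is.null(n_cells) && n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  stopifnot(frame_interval > 0, pixel_size > 0)
  structure(
    list(
      filename = filename,
      intersection_threshold = intersection_threshold,
      grain_size = grain_size,
      sd_threshold = sd_threshold,
      tolerance_t = as.integer(tolerance_t),
      tolerance_xy = tolerance_xy,
      use_watershed = isTRUE(as.logical(use_watershed)),
      volume_threshold = as.integer(volume_threshold),
      n_cells = n_cells,
      frame_interval = frame_interval,
      pixel_size = pixel_size
    ),
    class = "wave_config"
  )
}

#' @export
print.wave_config <- function(x, ...) {
  cat("<wave_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm, if (is.null(v)) "<unset>" else format(v)))
  }
  invisible(x)
}

# JSON key -> constructor argument. Keys follow the customary variables.json
# vocabulary; the three lower-case keys carry the optional calibration.
.config_keys <- c(
  Filename = "filename",
  Intersection_threshold = "intersection_threshold",
  Grain_size = "grain_size",
  SD_threshold = "sd_threshold",
  Tolerance_t = "tolerance_t",
  Tolerance_xy = "tolerance_xy",
  Use_watershed = "use_watershed",
  Volume_threshold = "volume_threshold",
  N_cells = "n_cells",
  Frame_interval = "frame_interval",
  Pixel_size = "pixel_size"
)

#' Load a configuration from a variables.json document
#'
#' Reads a flat JSON object whose keys are the pipeline variable names
#' (`Filename`, `Intersection_threshold`, `Grain_size`, `SD_threshold`,
#' `Tolerance_t`, `Tolerance_xy`, `Use_watershed`, `Volume_threshold`, plus
#' optional `N_cells`, `Frame_interval`, `Pixel_size`). Missing keys take
#' their defaults; unknown keys are rejected; `Use_watershed` accepts 0/1 or
#' a JSON boolean.
#'
#' @param path Path to the JSON file, or `NULL` for all defaults.
#' @return A [wave_config()] object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    return(wave_config())
  }
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("malformed config document: ", conditionMessage(e), call. = FALSE)
  )
  if (!is.list(vals) && length(vals) > 0) vals <- as.list(vals)
  unknown <- setdiff(names(vals), names(.config_keys))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- stats::setNames(vals, .config_keys[names(vals)])
  do.call(wave_config, args)
}

#' Serialise a configuration back to JSON
#'
#' Inverse of [load_config()]; the round trip is lossless.
#'
#' @param config A [wave_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "wave_config"))
  out <- config[.config_keys]
  names(out) <- names(.config_keys)
  out$Use_watershed <- as.integer(out$Use_watershed)
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
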