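#' Run the full event-analysis pipeline on one stack
#'
#' Optional pre-processing (motion correction first, then frame-mean
#' intensity correction, so zero-filled borders cannot bias the frame
#' means), then detection, 3D labelling, volume cleanup, cataloguing,
#' neighbour discovery, repeat classification and the recording summary.
#' The whole pipeline is a pure function of the stack and the
#' configuration: identical inputs give identical outputs.
#'
#' @param stack A [image_stack()] object.
#' @param config A [wave_config()] object.
#' @param motion_correct Apply rigid motion correction?
#' @param intensity_correct Apply frame-mean intensity correction?
#' @param motion_grid Subregion grid for [select_reference()].
#' @param recording_minutes Recording length for the incidence summary;
#'   derived from the stack when `NULL`.
#' @return An object of class `wave_pipeline`: list with `stack` (the
#'   processed stack), `config`, `mask`, `labels`, `catalog`, `neighbours`,
#'   `repeats`, `summary`, and `motion` (`NULL` unless motion correction
#'   ran).
#' @export
run_pipeline <- function(stack, config = wave_config(),
                         motion_correct = FALSE, intensity_correct = FALSE,
                         motion_grid = 8L, recording_minutes = NULL) {
  stopifnot(inherits(stack, "wave_stack"), inherits(config, "wave_config"))
  motion <- NULL
  if (motion_correct) {
    motion <- correct_motion(stack, grid = motion_grid)
    stack <- motion$stack
  }
  if (intensity_correct) stack <- correct_intensity(stack)
  mask <- extract_events(stack,
    grain_size = config$grain_size,
    sd_threshold = config$sd_threshold
  )
  labels <- create_masks(mask,
    use_watershed = config$use_watershed,
    intensities = stack
  )
  labels <- cleanup(labels, config$volume_threshold)
  catalog <- catalog_events(labels, stack)
  neighbours <- find_neighbours(catalog,
    tolerance_xy = config$tolerance_xy,
    tolerance_t = config$tolerance_t
  )
  repeats <- find_repeats(neighbours, catalog, config$intersection_threshold)
  if (is.null(recording_minutes)) {
    recording_minutes <- stack$n_frames * config$frame_interval / 60
  }
  summary <- summarise_recording(
    catalog, neighbours,
    n_cells = config$n_cells,
    recording_minutes = recording_minutes,
    pixel_size = config$pixel_size,
    frame_interval = config$frame_interval
  )
  structure(
    list(
      stack = stack, config = config, mask = mask, labels = labels,
      catalog = catalog, neighbours = neighbours, repeats = repeats,
      summary = summary, motion = motion
    ),
    class = "wave_pipeline"
  )
}

#' @export
print.wave_pipeline <- function(x, ...) {
  cat(sprintf(
    "<wave_pipeline> %d events, %d neighbour records\n",
    nrow(x$catalog$events), nrow(x$neighbours)
  ))
  print(x$summary)
  invisible(x)
}

#' Persist the pipeline artifacts under their customary filenames
#'
#' Writes, into `out_dir`: `waves.npy` (binary event mask, uint8),
#' `labelled_waves.npy` (int32 label volume), `black_and_white.tiff`
#' (binary TIFF rendering of the mask), `neighbours.csv`,
#' `neighbour_statistics.csv`, `repeats.csv`, `singles.csv`, plus
#' `events.csv` (the catalogue), `summary.csv` (recording metrics),
#' `motion_trace.csv` when motion correction ran, and a `manifest.json`
#' listing every file with its MD5 checksum. Reruns on identical input
#' produce identical files.
#'
#' @param pipeline A `wave_pipeline` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return Tibble manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.json`.
#' @export
persist_artifacts <- function(pipeline, out_dir) {
  stopifnot(inherits(pipeline, "wave_pipeline"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  write_npy(pipeline$mask + 0L, file.path(out_dir, "waves.npy"), dtype = "uint8")
  write_npy(pipeline$labels, file.path(out_dir, "labelled_waves.npy"), dtype = "int32")
  pages <- lapply(
    seq_len(dim(pipeline$mask)[1L]),
    function(t) pipeline$mask[t, , ] * 1
  )
  tiff::writeTIFF(pages, file.path(out_dir, "black_and_white.tiff"),
    bits.per.sample = 8L
  )
  generate_csv(pipeline$neighbours, pipeline$repeats, pipeline$catalog, out_dir)
  utils::write.csv(pipeline$catalog$events, file.path(out_dir, "events.csv"),
    row.names = FALSE
  )
  utils::write.csv(tibble::as_tibble(unclass(pipeline$summary)),
    file.path(out_dir, "summary.csv"),
    row.names = FALSE
  )
  if (!is.null(pipeline$motion)) {
    utils::write.csv(pipeline$motion$trace,
      file.path(out_dir, "motion_trace.csv"),
      row.names = FALSE
    )
  }
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Process a TIFF file or a directory of TIFFs
#'
#' The file-level entry point behind the command-line interface. With a
#' directory input and `filename = "All"` every `.tif`/`.tiff` file is
#' processed in lexicographic name order, each into its own subdirectory of
#' `out_dir`.
#'
#' @param input A TIFF file or a directory containing TIFFs.
#' @param config A [wave_config()] object.
#' @param out_dir Output directory root.
#' @param ... Passed on to [run_pipeline()].
#' @return Invisibly, a named list of `wave_pipeline` results.
#' @export
process_path <- function(input, config = wave_config(), out_dir, ...) {
  if (dir.exists(input)) {
    tiffs <- sort(list.files(input, pattern = "\\.tiff?$", ignore.case = TRUE))
    if (!identical(config$filename, "All")) {
      tiffs <- intersect(tiffs, config$filename)
    }
    if (length(tiffs) == 0L) stop("no TIFF files to process in ", input, call. = FALSE)
    res <- lapply(tiffs, function(f) {
      st <- read_stack(file.path(input, f),
        frame_interval = config$frame_interval,
        pixel_size = config$pixel_size
      )
      p <- run_pipeline(st, config, ...)
      persist_artifacts(p, file.path(out_dir, tools::file_path_sans_ext(f)))
      p
    })
    names(res) <- tiffs
    invisible(res)
  } else {
    st <- read_stack(input,
      frame_interval = config$frame_interval,
      pixel_size = config$pixel_size
    )
    p <- run_pipeline(st, config, ...)
    persist_artifacts(p, out_dir)
    invisible(stats::setNames(list(p), basename(input)))
  }
}
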