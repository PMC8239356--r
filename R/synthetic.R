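#' Describe a planted calcium event
#'
#' One synthetic transient: a spatial Gaussian footprint whose brightness
#' rises and decays exponentially around an onset frame. Optional extras
#' emulate the two propagation phenomena the pipeline quantifies: a drift
#' velocity moves the footprint across the field (an intercellular wave),
#' and a repeat schedule fires the same site again (repeated events).
#'
#' @param y,x Centre pixel (0-based).
#' @param onset Onset frame (0-based).
#' @param amplitude Peak amplitude in multiples of the baseline noise SD.
#' @param radius Spatial Gaussian sd in pixels.
#' @param tau_rise,tau_decay Rise / decay time constants in frames.
#' @param velocity Optional `c(vy, vx)` px/frame footprint drift.
#' @param repeat_onsets Optional vector of extra onset frames at this site.
#' @return A `planted_event` list.
#' @export
planted_event <- function(y, x, onset, amplitude = 10, radius = 4,
                          tau_rise = 1.5, tau_decay = 4,
                          velocity = NULL, repeat_onsets = NULL) {
  stopifnot(amplitude > 0, radius >= 1, onset >= 0)
  structure(
    list(
      y = y, x = x, onset = onset, amplitude = amplitude, radius = radius,
      tau_rise = tau_rise, tau_decay = tau_decay, velocity = velocity,
      repeat_onsets = repeat_onsets
    ),
    class = "planted_event"
  )
}

#' Describe a synthetic recording
#'
#' A scene specification fully determines the generated stack given its
#' seed. Defaults emulate a low-noise GCaMP6f recording shrunk for desk-side
#' verification: 160 x 160 px, 300 frames at 5 frames/s, baseline 100 AU,
#' additive Gaussian noise of SD 2 AU.
#'
#' @param n_frames,height,width Stack dimensions.
#' @param baseline Baseline fluorescence level (AU).
#' @param noise_sd Additive Gaussian noise SD (AU); 0 for noise-free.
#' @param bleach_rate Fractional baseline loss per frame (photobleaching),
#'   e.g. 0.01 for 1%/frame.
#' @param drift Optional tibble/data.frame (`frame`, `dy`, `dx`): integer
#'   rigid shift applied to each listed frame (0-based frames).
#' @param events List of [planted_event()]s.
#' @param seed RNG seed; the (spec, seed) pair reproduces the stack bitwise.
#' @param frame_interval,pixel_size Calibration, see [image_stack()].
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_frames = 300L, height = 160L, width = 160L,
                       baseline = 100, noise_sd = 2, bleach_rate = 0,
                       drift = NULL, events = list(), seed = 1L,
                       frame_interval = 0.2, pixel_size = 0.586) {
  for (e in events) {
    stopifnot(inherits(e, "planted_event"))
    if (e$y < 0 || e$y >= height || e$x < 0 || e$x >= width ||
      any(c(e$onset, e$repeat_onsets) >= n_frames)) {
      stop("planted event outside the recording bounds", call. = FALSE)
    }
  }
  structure(
    list(
      n_frames = as.integer(n_frames), height = as.integer(height),
      width = as.integer(width), baseline = baseline, noise_sd = noise_sd,
      bleach_rate = bleach_rate, drift = drift, events = events,
      seed = as.integer(seed), frame_interval = frame_interval,
      pixel_size = pixel_size
    ),
    class = "scene_spec"
  )
}

# temporal envelope, normalised to continuous peak 1
.envelope <- function(dt, tau_rise, tau_decay) {
  g <- ifelse(dt < 0, 0, (1 - exp(-dt / tau_rise)) * exp(-dt / tau_decay))
  peak_t <- tau_rise * log(1 + tau_decay / tau_rise)
  gmax <- (1 - exp(-peak_t / tau_rise)) * exp(-peak_t / tau_decay)
  g / gmax
}

# render one transient into `acc` (array T x H x W, 0-based event coords),
# returning the modified array; also used to derive ground truth
.render_transient <- function(acc, ev, onset, spec) {
  r <- ev$radius
  ext <- ceiling(3 * r)
  # amplitude is stated in baseline-noise-SD multiples; for noise-free
  # scenes one AU plays the unit role
  amp <- ev$amplitude * if (spec$noise_sd > 0) spec$noise_sd else 1
  frames <- onset:(spec$n_frames - 1L)
  g <- .envelope(frames - onset, ev$tau_rise, ev$tau_decay)
  live <- frames[g > 1e-3]
  g <- g[g > 1e-3]
  for (i in seq_along(live)) {
    t <- live[i]
    cy <- ev$y + if (is.null(ev$velocity)) 0 else ev$velocity[1L] * (t - onset)
    cx <- ev$x + if (is.null(ev$velocity)) 0 else ev$velocity[2L] * (t - onset)
    ys <- max(0L, floor(cy - ext)):min(spec$height - 1L, ceiling(cy + ext))
    xs <- max(0L, floor(cx - ext)):min(spec$width - 1L, ceiling(cx + ext))
    if (length(ys) == 0L || length(xs) == 0L) next
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    acc[t + 1L, ys + 1L, xs + 1L] <- acc[t + 1L, ys + 1L, xs + 1L] +
      amp * g[i] * exp(-d2 / (2 * r^2))
  }
  acc
}

#' Generate a synthetic recording with ground truth
#'
#' Builds `baseline * bleach(t) + sum(events) + noise`, then applies the
#' rigid drift schedule. Every planted transient (repeats included) becomes
#' one ground-truth row; its reference volume is the voxel count of its
#' noise-free rendering above half its maximum (detector-independent), and
#' repeats at one site share a `chain_id`.
#'
#' @param spec A [scene_spec()].
#' @return List with `stack` (a [image_stack()]) and `truth` (tibble:
#'   `event`, `chain_id`, `y`, `x`, `onset`, `amplitude`, `radius`,
#'   `volume_halfmax`).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  dm <- c(spec$n_frames, spec$height, spec$width)
  bleach <- (1 - spec$bleach_rate)^(seq_len(spec$n_frames) - 1L)
  signal <- array(0, dm)
  truth <- list()
  n <- 0L
  chain <- 0L
  for (ev in spec$events) {
    chain <- chain + 1L
    onsets <- sort(c(ev$onset, ev$repeat_onsets))
    for (on in onsets) {
      clean <- .render_transient(array(0, dm), ev, on, spec)
      n <- n + 1L
      truth[[n]] <- tibble::tibble(
        event = n,
        chain_id = if (length(onsets) > 1L) chain else NA_integer_,
        y = ev$y, x = ev$x, onset = on,
        amplitude = ev$amplitude, radius = ev$radius,
        volume_halfmax = sum(clean >= max(clean) / 2)
      )
      signal <- signal + clean
    }
  }
  set.seed(spec$seed)
  data <- spec$baseline * rep(bleach, times = spec$height * spec$width)
  data <- array(data, dm) + signal
  if (spec$noise_sd > 0) {
    data <- data + array(stats::rnorm(prod(dm), sd = spec$noise_sd), dm)
  }
  if (!is.null(spec$drift)) {
    for (r in seq_len(nrow(spec$drift))) {
      t <- spec$drift$frame[r] + 1L
      data[t, , ] <- .translate_frame(
        data[t, , ],
        spec$drift$dy[r], spec$drift$dx[r]
      )
    }
  }
  data <- pmax(data, 0)
  list(
    stack = image_stack(data,
      frame_interval = spec$frame_interval,
      pixel_size = spec$pixel_size
    ),
    truth = if (n > 0L) dplyr::bind_rows(truth) else tibble::tibble(
      event = integer(), chain_id = integer(), y = double(), x = double(),
      onset = integer(), amplitude = double(), radius = double(),
      volume_halfmax = integer()
    )
  )
}

#' Standard verification scene: isolated events on a jittered grid
#'
#' Twenty well-separated transients at the default study conditions
#' (amplitude 10 noise-SD, radius 4 px, reference volumes well above the
#' cleanup threshold), onsets spread over the recording. Used for detector
#' recall/precision/localisation checks.
#'
#' @param n_events Number of events (placed on a 5 x 4 grid by default).
#' @param seed RNG seed (placement jitter, onsets, noise).
#' @return A [scene_spec()].
#' @export
example_scene <- function(n_events = 20L, seed = 1L) {
  set.seed(seed)
  gx <- rep(seq(16, 144, by = 32), times = 4)[seq_len(n_events)]
  gy <- rep(seq(20, 140, by = 40), each = 5)[seq_len(n_events)]
  jit <- function(n) sample(-6:6, n, replace = TRUE)
  onsets <- sample(10:260, n_events)
  events <- lapply(seq_len(n_events), function(i) {
    planted_event(
      y = gy[i] + jit(1), x = gx[i] + jit(1), onset = onsets[i]
    )
  })
  scene_spec(events = events, seed = seed)
}

#' Propagating-wave scene with known speed
#'
#' A chain of cells firing in sequence: `n_sites` sites spaced `spacing_px`
#' apart along x, each igniting `delay_frames` after its predecessor. The
#' planted intercellular propagation speed is
#' `spacing_px * pixel_size / (delay_frames * frame_interval)`.
#'
#' @param n_sites Number of sites in the chain.
#' @param spacing_px Centre-to-centre spacing in pixels.
#' @param delay_frames Inter-site onset delay in frames.
#' @param seed RNG seed.
#' @return A [scene_spec()].
#' @export
wave_scene <- function(n_sites = 5L, spacing_px = 30, delay_frames = 3L, seed = 1L) {
  events <- lapply(seq_len(n_sites), function(i) {
    planted_event(
      y = 60, x = 20 + (i - 1L) * spacing_px,
      onset = 50L + (i - 1L) * delay_frames
    )
  })
  scene_spec(
    height = 120L, width = 40 + n_sites * spacing_px,
    events = events, seed = seed
  )
}

#' Deterministic boundary-semantics fixtures
#'
#' Noise-free minimal inputs that put every decision boundary of the
#' pipeline's parameters on the table:
#' \describe{
#'   \item{volumes}{a label array with eleven events of exactly 35..45
#'     voxels (cleanup boundary), plus the matching intensity stack.}
#'   \item{separations}{per separation 40..60 px, a catalogue of two
#'     simultaneous single-voxel events that distance apart in x
#'     (`tolerance_xy` boundary).}
#'   \item{time_gaps}{per gap 1..10 frames, a catalogue of two co-located
#'     single-voxel events that many frames apart (`tolerance_t` boundary).}
#'   \item{overlaps}{per fraction 0.70, 0.75, ..., 0.90, a catalogue of two
#'     equal-area (20 px) footprints with exactly that overlap fraction
#'     (`intersection_threshold` boundary).}
#'   \item{deflections}{per multiplier k = 3.0, 3.5, ..., 7.0, a single-pixel
#'     stack whose trace holds 100 alternating baseline samples (10 +/- 1)
#'     and one spike at `10 + k * sd(baseline part)` (`sd_threshold`
#'     boundary; detection uses full-trace statistics, spike included).}
#' }
#'
#' @return A named list of fixture sets; each element carries the inputs
#'   and the ground truth needed to verify the corresponding boundary.
#' @export
make_boundary_fixtures <- function() {
  # (a) volumes 35..45: horizontal runs of v voxels in one frame each, far apart
  vols <- 35:45
  lab_a <- array(0L, dim = c(24L, 80L, 50L))
  stack_a <- array(1, dim = dim(lab_a))
  for (i in seq_along(vols)) {
    # v voxels as up to five 9-wide rows plus a remainder row, one frame
    # each; bands separated in y and t so events stay disconnected
    v <- vols[i]
    full_rows <- v %/% 9L
    rem <- v %% 9L
    t <- 2L * i
    y0 <- (i - 1L) * 7L + 1L
    if (full_rows > 0L) lab_a[t, y0:(y0 + full_rows - 1L), 1:9] <- i
    if (rem > 0L) lab_a[t, y0 + full_rows, seq_len(rem)] <- i
  }
  volumes <- list(
    labels = lab_a,
    stack = image_stack(stack_a),
    truth = tibble::tibble(id = seq_along(vols), volume = vols)
  )

  two_voxel_catalog <- function(t1, y1, x1, t2, y2, x2, nt, h, w) {
    lab <- array(0L, dim = c(nt, h, w))
    lab[t1, y1, x1] <- 1L
    lab[t2, y2, x2] <- 2L
    st <- image_stack(array(1, dim = dim(lab)))
    catalog_events(lab, st)
  }

  # (b) simultaneous single-voxel pairs at x separations 40..60
  separations <- lapply(40:60, function(s) {
    list(
      separation = s,
      catalog = two_voxel_catalog(2L, 5L, 5L, 2L, 5L, 5L + s, 3L, 10L, 70L)
    )
  })

  # (c) co-located single-voxel pairs at frame gaps 1..10
  time_gaps <- lapply(1:10, function(g) {
    list(
      gap = g,
      catalog = two_voxel_catalog(2L, 5L, 5L, 2L + g, 5L, 5L, 13L, 10L, 10L)
    )
  })

  # (d) equal-area (20 px) footprints with overlap fractions 0.70..0.90
  overlaps <- lapply(seq(0.70, 0.90, by = 0.05), function(f) {
    c_shared <- round(f * 20)
    lab <- array(0L, dim = c(4L, 5L, 50L))
    lab[2L, 2L, 1:20] <- 1L
    lab[3L, 2L, (21L - c_shared):(40L - c_shared)] <- 2L
    st <- image_stack(array(1, dim = dim(lab)))
    list(fraction = c_shared / 20, catalog = catalog_events(lab, st))
  })

  # (e) single-pixel traces: alternating 10 +/- 1 baseline, one k*sd spike
  base <- 10 + rep(c(1, -1), length.out = 100L)
  sd_base <- stats::sd(base)
  deflections <- lapply(seq(3, 7, by = 0.5), function(k) {
    trace <- c(base, 10 + k * sd_base)
    list(
      k = k,
      trace = trace,
      stack = image_stack(array(trace, dim = c(length(trace), 1L, 1L)))
    )
  })

  list(
    volumes = volumes, separations = separations, time_gaps = time_gaps,
    overlaps = overlaps, deflections = deflections
  )
}
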