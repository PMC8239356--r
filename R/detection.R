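#' Detect calcium events by grain-wise temporal SD thresholding
#'
#' Tiles every frame into non-overlapping `grain_size` x `grain_size` pixel
#' blocks ("grains"; trailing partial blocks keep their actual pixel count).
#' For each grain the temporal trace of its block-mean intensity is taken
#' over the whole recording, with trace mean `mu` and trace SD `sigma`
#' (sample SD, events included). At frame `t` the grain's pixels are
#' foreground iff `block_mean(t) >= mu + sd_threshold * sigma`; grains with
#' `sigma = 0` are always background. All pixels of a grain switch together,
#' so no region-of-interest drawing is needed: events appear wherever the
#' signal exceeds its own temporal variability.
#'
#' @param stack A [image_stack()] object.
#' @param grain_size Block side in pixels (power of two), default 1.
#' @param sd_threshold Positive SD multiplier, default 5.
#' @return A logical 3D array (`frame`, `row`, `column`) — the binary event
#'   mask, same shape as the stack.
#' @export
extract_events <- function(stack, grain_size = 1L, sd_threshold = 5) {
  stopifnot(inherits(stack, "wave_stack"))
  g <- as.integer(grain_size)
  if (g < 1L || bitwAnd(g, g - 1L) != 0L) {
    stop("`grain_size` must be a power of two", call. = FALSE)
  }
  if (sd_threshold <= 0) stop("`sd_threshold` must be positive", call. = FALSE)
  h <- stack$height
  w <- stack$width
  if (g > h || g > w) {
    stop("`grain_size` exceeds the frame dimensions", call. = FALSE)
  }
  nby <- ceiling(h / g)
  by <- ceiling(seq_len(h) / g)
  bx <- ceiling(seq_len(w) / g)
  bid <- as.vector(outer(by, bx, function(a, b) (b - 1L) * nby + a))
  nt <- stack$n_frames
  px <- matrix(stack$data, nrow = nt) # frames x pixels, pixels in (y,x) col-major
  counts <- tabulate(bid, nbins = max(bid))
  traces <- rowsum(t(px), bid) / counts # blocks x frames
  mu <- rowMeans(traces)
  sigma <- sqrt(rowSums((traces - mu)^2) / (nt - 1L))
  fg <- traces >= mu + sd_threshold * sigma # blocks x frames
  fg[sigma == 0, ] <- FALSE
  mask_px <- t(fg[bid, , drop = FALSE]) # frames x pixels
  array(mask_px, dim = c(nt, h, w))
}

# 26-neighbourhood offsets in (t, y, x)
.offsets26 <- local({
  o <- as.matrix(expand.grid(dt = -1:1, dy = -1:1, dx = -1:1))
  o[rowSums(abs(o)) > 0L, , drop = FALSE]
})

# linear index into an array [T, H, W] from coordinate vectors
.lin3 <- function(t, y, x, dm) t + (y - 1L) * dm[1L] + (x - 1L) * dm[1L] * dm[2L]

#' Label 26-connected spatiotemporal components
#'
#' Groups adjacent foreground voxels into single calcium events in (x, y, t)
#' space, using the full 26-neighbourhood (face, edge and corner contacts,
#' including diagonal moves in time — propagating waves travel diagonally in
#' x-y-t). Events are numbered 1..K by the (t, y, x)-lexicographic order of
#' their first foreground voxel, so IDs are reproducible across runs.
#'
#' @param mask Logical 3D array (`frame`, `row`, `column`).
#' @return Integer 3D array: 0 = background, 1..K = event IDs.
#' @keywords internal
#' @export
label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (length(idx) == 0L) {
    return(lab)
  }
  ai <- arrayInd(idx, dm)
  seeds <- idx[order(ai[, 1L], ai[, 2L], ai[, 3L])]
  k <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    k <- k + 1L
    lab[s] <- k
    frontier <- s
    while (length(frontier) > 0L) {
      fi <- arrayInd(frontier, dm)
      nxt <- integer(0)
      for (j in seq_len(nrow(.offsets26))) {
        tt <- fi[, 1L] + .offsets26[j, 1L]
        yy <- fi[, 2L] + .offsets26[j, 2L]
        xx <- fi[, 3L] + .offsets26[j, 3L]
        ok <- tt >= 1L & tt <= dm[1L] & yy >= 1L & yy <= dm[2L] & xx >= 1L & xx <= dm[3L]
        if (!any(ok)) next
        lin <- .lin3(tt[ok], yy[ok], xx[ok], dm)
        lin <- lin[mask[lin] & lab[lin] == 0L]
        if (length(lin) > 0L) {
          lab[lin] <- k
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# renumber labels 1..K by first (t,y,x)-lexicographic voxel of each region
.relabel_lex <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(lab)
  }
  ai <- arrayInd(idx, dim(lab))
  ord <- order(ai[, 1L], ai[, 2L], ai[, 3L])
  first_seen <- idx[ord][!duplicated(lab[idx[ord]])]
  map <- integer(max(lab))
  map[lab[first_seen]] <- seq_along(first_seen)
  lab[idx] <- map[lab[idx]]
  lab
}

# separable Gaussian smoothing of a 3D array (sd in voxels per axis),
# truncated at 3 sd with edge renormalisation
.gauss_smooth3 <- function(a, sd = c(1, 1, 1)) {
  sm_axis <- function(a, axis, s) {
    if (s <= 0) {
      return(a)
    }
    n <- dim(a)[axis]
    r <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(-r:r, sd = s)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, i - r):pmin(n, i + r)
      kk <- kern[j - i + r + 1L]
      K[i, j] <- kk / sum(kk)
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    out <- array(K %*% m, dim = dim(ap))
    aperm(out, order(perm))
  }
  for (ax in 1:3) a <- sm_axis(a, ax, sd[ax])
  a
}

# split one labelled component by seeded watershed on the (smoothed)
# intensity: seeds at regional maxima, Meyer-style flooding of the inverted
# relief, deterministic ties by lowest (t,y,x) lexicographic rank
.watershed_component <- function(vox_lin, dm, smooth) {
  n <- length(vox_lin)
  if (n == 1L) {
    return(rep(1L, n))
  }
  ai <- arrayInd(vox_lin, dm)
  lex <- order(ai[, 1L], ai[, 2L], ai[, 3L]) # lex[i] = position of i-th lowest
  lex_rank <- integer(n)
  lex_rank[lex] <- seq_len(n)
  val <- smooth[vox_lin]
  lookup <- stats::setNames(seq_len(n), as.character(vox_lin))
  # neighbour lists (indices into vox_lin) restricted to the component
  nb <- vector("list", n)
  for (j in seq_len(nrow(.offsets26))) {
    tt <- ai[, 1L] + .offsets26[j, 1L]
    yy <- ai[, 2L] + .offsets26[j, 2L]
    xx <- ai[, 3L] + .offsets26[j, 3L]
    ok <- tt >= 1L & tt <= dm[1L] & yy >= 1L & yy <= dm[2L] & xx >= 1L & xx <= dm[3L]
    lin <- rep(NA_integer_, n)
    lin[ok] <- .lin3(tt[ok], yy[ok], xx[ok], dm)
    hit <- lookup[as.character(lin)]
    for (i in which(!is.na(hit))) nb[[i]] <- c(nb[[i]], unname(hit[i]))
  }
  # regional maxima: voxels not dominated by any neighbour; plateaus
  # (equal-valued connected candidates) collapse to one seed
  cand <- vapply(seq_len(n), function(i) all(val[nb[[i]]] <= val[i]), logical(1))
  seed_lab <- integer(n)
  ns <- 0L
  for (i in lex[cand[lex]]) { # visit candidates in lex order
    if (seed_lab[i] != 0L) next
    ns <- ns + 1L
    seed_lab[i] <- ns
    q <- i
    while (length(q) > 0L) {
      cur <- q[1L]
      q <- q[-1L]
      for (v in nb[[cur]]) {
        if (cand[v] && seed_lab[v] == 0L && val[v] == val[cur]) {
          seed_lab[v] <- ns
          q <- c(q, v)
        }
      }
    }
  }
  if (ns <= 1L) {
    return(rep(1L, n))
  }
  # Meyer flooding: repeatedly take the unassigned voxel of highest
  # intensity adjacent to the assigned set
  assigned <- seed_lab
  repeat {
    front <- which(assigned == 0L &
      vapply(nb, function(v) any(assigned[v] > 0L), logical(1)))
    if (length(front) == 0L) break
    best <- front[order(-val[front], lex_rank[front])][1L]
    anb <- nb[[best]][assigned[nb[[best]]] > 0L]
    pick <- anb[order(-val[anb], lex_rank[anb])][1L]
    assigned[best] <- assigned[pick]
  }
  assigned[assigned == 0L] <- 1L # isolated remnants (none expected)
  assigned
}

#' Assign foreground voxels to labelled calcium events
#'
#' Connected-component labelling of the binary event mask with full
#' 26-neighbourhood connectivity in (x, y, t). With `use_watershed = TRUE`
#' each component is further split by a 3D watershed seeded at the regional
#' maxima of the Gaussian-smoothed intensity (sd 1 px and 1 frame) within
#' the component, so touching events with distinct intensity peaks get
#' distinct IDs. Watershed neither creates nor deletes foreground voxels.
#'
#' @param mask Logical 3D array from [extract_events()].
#' @param use_watershed Split touching events at intensity saddles?
#' @param intensities The [image_stack()] the mask was computed from;
#'   required when `use_watershed = TRUE`.
#' @return Integer 3D label array (`LabelVolume`): 0 = background, event
#'   IDs 1..K numbered by first (t, y, x)-lexicographic voxel.
#' @export
create_masks <- function(mask, use_watershed = FALSE, intensities = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("`mask` must be a logical 3D array", call. = FALSE)
  }
  lab <- label_components(mask)
  if (!use_watershed || max(lab) == 0L) {
    return(lab)
  }
  stopifnot(inherits(intensities, "wave_stack"))
  if (!identical(dim(intensities$data), dim(mask))) {
    stop("mask and intensity stack shapes differ", call. = FALSE)
  }
  dm <- dim(mask)
  smooth <- .gauss_smooth3(intensities$data, sd = c(1, 1, 1))
  out <- array(0L, dm)
  nxt <- 0L
  for (k in seq_len(max(lab))) {
    vox <- which(lab == k)
    sub <- .watershed_component(vox, dm, smooth)
    out[vox] <- sub + nxt
    nxt <- nxt + max(sub)
  }
  .relabel_lex(out)
}

#' Remove noise-associated events below a volume threshold
#'
#' Drops every event whose voxel count is strictly smaller than
#' `volume_threshold` (an event of exactly the threshold volume is kept) and
#' renumbers the survivors contiguously, preserving their original order.
#'
#' @param labels Integer 3D label array from [create_masks()].
#' @param volume_threshold Minimum surviving volume in voxels, default 40.
#' @return A label array with K' <= K contiguous labels.
#' @export
cleanup <- function(labels, volume_threshold = 40L) {
  k <- max(labels)
  if (k == 0L || volume_threshold <= 0L) {
    return(labels)
  }
  vols <- tabulate(labels[labels > 0L], nbins = k)
  keep <- which(vols >= volume_threshold)
  map <- integer(k)
  map[keep] <- seq_along(keep)
  idx <- which(labels > 0L)
  labels[idx] <- map[labels[idx]]
  labels
}
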