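# Independent oracles and fixture builders shared across the suite.
# These deliberately use different algorithms from the package internals.

# connected-component labelling by iterated min-label propagation over the
# 26-neighbourhood: every foreground voxel starts with a unique label and
# repeatedly adopts the minimum label in its neighbourhood until fixpoint.
oracle_label <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  lab <- array(0L, dm)
  if (n == 0L) {
    return(lab)
  }
  ai <- arrayInd(idx, dm)
  pos <- integer(prod(dm))
  pos[idx] <- seq_len(n)
  offs <- as.matrix(expand.grid(dt = -1:1, dy = -1:1, dx = -1:1))
  # neighbour matrix: n x 27 positions into 1..n (NA outside / background)
  nb <- matrix(NA_integer_, n, nrow(offs))
  for (j in seq_len(nrow(offs))) {
    tt <- ai[, 1L] + offs[j, 1L]
    yy <- ai[, 2L] + offs[j, 2L]
    xx <- ai[, 3L] + offs[j, 3L]
    ok <- tt >= 1L & tt <= dm[1L] & yy >= 1L & yy <= dm[2L] & xx >= 1L & xx <= dm[3L]
    lin <- tt[ok] + (yy[ok] - 1L) * dm[1L] + (xx[ok] - 1L) * dm[1L] * dm[2L]
    p <- pos[lin]
    p[p == 0L] <- NA_integer_
    nb[ok, j] <- p
  }
  cur <- seq_len(n)
  repeat {
    cols <- lapply(seq_len(ncol(nb)), function(j) {
      v <- cur[nb[, j]]
      v[is.na(v)] <- .Machine$integer.max
      v
    })
    nxt <- do.call(pmin, cols)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  lab[idx] <- match(cur, sort(unique(cur)))
  lab
}

# map labels to a canonical partition signature (sets of voxel indices)
partition_signature <- function(lab) {
  idx <- which(lab > 0L)
  unname(lapply(
    split(idx, lab[idx]),
    sort
  ))[order(vapply(split(idx, lab[idx]), min, numeric(1)))]
}

# exhaustive all-pairs neighbour oracle: recompute centroids, half-widths
# and box membership directly from voxel lists
oracle_neighbours <- function(catalog, tolerance_xy, tolerance_t) {
  k <- nrow(catalog$events)
  out <- NULL
  for (i in seq_len(k)) {
    vi <- catalog$voxels[[i]]
    w <- vi[, "intensity"]
    if (sum(w) <= 0) w <- rep(1, nrow(vi))
    cen <- c(
      sum((vi[, "t"] - 1) * w), sum((vi[, "y"] - 1) * w),
      sum((vi[, "x"] - 1) * w)
    ) / sum(w)
    half <- c(
      max(abs(vi[, "t"] - 1 - cen[1])) + tolerance_t,
      max(abs(vi[, "y"] - 1 - cen[2])) + tolerance_xy,
      max(abs(vi[, "x"] - 1 - cen[3])) + tolerance_xy
    )
    for (j in seq_len(k)) {
      if (i == j) next
      vj <- catalog$voxels[[j]]
      inside <- abs(vj[, "t"] - 1 - cen[1]) <= half[1] &
        abs(vj[, "y"] - 1 - cen[2]) <= half[2] &
        abs(vj[, "x"] - 1 - cen[3]) <= half[3]
      if (any(inside)) out <- rbind(out, c(i, j))
    }
  }
  out
}

# reproducible random boolean mask
random_mask <- function(dims, p, seed) {
  set.seed(seed)
  array(stats::runif(prod(dims)) < p, dim = dims)
}

# stack whose frames are given matrices
stack_from_frames <- function(...) {
  frames <- list(...)
  h <- nrow(frames[[1]])
  w <- ncol(frames[[1]])
  dat <- array(0, dim = c(length(frames), h, w))
  for (i in seq_along(frames)) dat[i, , ] <- frames[[i]]
  image_stack(dat)
}

# static smoothly-textured field for registration fixtures
textured_frame <- function(h, w, seed) {
  set.seed(seed)
  tex <- array(matrix(stats::runif(h * w, 50, 150), h, w), dim = c(1, h, w))
  astrowave:::.gauss_smooth3(tex, c(0, 2, 2))[1, , ]
}

# random scattered-event catalogue on a small grid (for oracle comparisons)
random_catalog <- function(n_events, seed, dims = c(40L, 60L, 60L)) {
  set.seed(seed)
  lab <- array(0L, dim = dims)
  placed <- 0L
  while (placed < n_events) {
    placed <- placed + 1L
    t0 <- sample(dims[1L] - 3L, 1L)
    y0 <- sample(dims[2L] - 4L, 1L)
    x0 <- sample(dims[3L] - 4L, 1L)
    lab[t0:(t0 + sample(0:2, 1L)), y0:(y0 + sample(0:3, 1L)),
      x0:(x0 + sample(0:3, 1L))] <- placed
  }
  # overwrites may orphan earlier labels entirely; keep only non-empty,
  # contiguously renumbered (mirrors cleanup(0) semantics)
  present <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], present)
  st <- image_stack(array(stats::runif(prod(dims), 1, 10), dim = dims))
  catalog_events(lab, st)
}
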