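test_that("xy tolerance is the inclusive neighbourhood boundary", {
  fx <- make_boundary_fixtures()$separations
  for (f in fx) {
    nb <- find_neighbours(f$catalog, tolerance_xy = 50, tolerance_t = 5)
    if (f$separation <= 50) {
      expect_setequal(paste(nb$event_id, nb$neighbour_id), c("1 2", "2 1"))
      expect_equal(nb$centre_distance_xy_px, rep(f$separation, 2))
    } else {
      expect_equal(nrow(nb), 0L, info = paste("separation", f$separation))
    }
  }
})

test_that("t tolerance is the inclusive neighbourhood boundary", {
  fx <- make_boundary_fixtures()$time_gaps
  for (f in fx) {
    nb <- find_neighbours(f$catalog, tolerance_xy = 50, tolerance_t = 5)
    if (f$gap <= 5) {
      expect_setequal(nb$delta_onset_frames, c(f$gap, -f$gap))
    } else {
      expect_equal(nrow(nb), 0L, info = paste("gap", f$gap))
    }
  }
})

test_that("neighbour discovery matches the exhaustive all-pairs oracle", {
  for (seed in c(3, 8, 15)) {
    cat_ev <- random_catalog(n_events = 12, seed = seed)
    for (tol in list(c(10, 3), c(0, 0), c(25, 6))) {
      nb <- find_neighbours(cat_ev, tolerance_xy = tol[1], tolerance_t = tol[2])
      got <- nb[order(nb$event_id, nb$neighbour_id), c("event_id", "neighbour_id")]
      ref <- oracle_neighbours(cat_ev, tol[1], tol[2])
      if (is.null(ref)) {
        expect_equal(nrow(got), 0L)
      } else {
        ref <- ref[order(ref[, 1], ref[, 2]), , drop = FALSE]
        expect_equal(as.matrix(got), ref, ignore_attr = TRUE)
      }
    }
  }
})

test_that("A-B-C geometry records exactly the qualifying ordered pairs", {
  lab <- array(0L, c(3, 5, 200))
  lab[2, 3, 10] <- 1L # A
  lab[2, 3, 50] <- 2L # B: 40 px from A, 40 px from C
  lab[2, 3, 90] <- 3L # C: 80 px from A
  cat_ev <- catalog_events(lab, image_stack(array(1, dim(lab))))
  nb <- find_neighbours(cat_ev, tolerance_xy = 50, tolerance_t = 5)
  expect_setequal(
    paste(nb$event_id, nb$neighbour_id),
    c("1 2", "2 1", "2 3", "3 2")
  )
})

test_that("repeat classification is strict at the intersection threshold", {
  fx <- make_boundary_fixtures()$overlaps
  for (f in fx) {
    nb <- find_neighbours(f$catalog, 50, 5)
    rp <- find_repeats(nb, f$catalog, intersection_threshold = 0.8)
    want <- if (f$fraction > 0.8) "repeat" else "single"
    expect_equal(rp$classification$category, rep(want, 2),
      info = paste("fraction", f$fraction)
    )
  }
  # recomputed by direct set arithmetic: the 0.75 fixture overlaps by 15/20
  f75 <- fx[[2]]
  pa <- f75$catalog$projections[[1]]
  pb <- f75$catalog$projections[[2]]
  inter <- length(intersect(paste(pa[, 1], pa[, 2]), paste(pb[, 1], pb[, 2])))
  expect_equal(inter / min(nrow(pa), nrow(pb)), 0.75)
})

test_that("identical and disjoint footprints classify as repeat and single", {
  lab <- array(0L, c(6, 10, 40))
  lab[2, 2:4, 2:4] <- 1L
  lab[4, 2:4, 2:4] <- 2L # identical footprint, f = 1
  lab[3, 8, 30] <- 3L # disjoint
  cat_ev <- catalog_events(lab, image_stack(array(1, dim(lab))))
  nb <- find_neighbours(cat_ev, 50, 5)
  rp <- find_repeats(nb, cat_ev, 0.8)
  expect_equal(rp$classification$category, c("repeat", "repeat", "single"))
  expect_equal(rp$classification$chain_id, c(1L, 1L, NA_integer_))
})

test_that("repeat chains merge transitively and gaps follow onsets", {
  lab <- array(0L, c(30, 8, 8))
  lab[11, 2:4, 2:4] <- 1L
  lab[14, 2:4, 2:4] <- 2L
  lab[19, 2:4, 2:4] <- 3L # neighbour of 2 (gap 5) but not of 1 (gap 8 > box)
  cat_ev <- catalog_events(lab, image_stack(array(1, dim(lab))))
  nb <- find_neighbours(cat_ev, tolerance_xy = 5, tolerance_t = 5)
  rp <- find_repeats(nb, cat_ev, 0.8)
  expect_equal(rp$classification$category, rep("repeat", 3))
  expect_equal(rp$chains$gap_from_previous_frames, c(NA, 3L, 5L))
})

test_that("raising the intersection threshold never adds repeats", {
  fx <- make_boundary_fixtures()$overlaps
  for (f in fx) {
    nb <- find_neighbours(f$catalog, 50, 5)
    n_rep <- vapply(c(0.5, 0.7, 0.8, 0.9, 1.0), function(thr) {
      sum(find_repeats(nb, f$catalog, thr)$classification$category == "repeat")
    }, numeric(1))
    expect_true(all(diff(n_rep) <= 0))
  }
})

test_that("the four CSV outputs carry the expected rows", {
  # one chain of 3 repeats + 2 singles
  lab <- array(0L, c(70, 10, 60))
  lab[11, 2:4, 2:4] <- 1L
  lab[16, 2:4, 2:4] <- 2L
  lab[21, 2:4, 2:4] <- 3L
  lab[15, 8, 50] <- 4L
  lab[60, 8, 50] <- 5L
  cat_ev <- catalog_events(lab, image_stack(array(1, dim(lab))))
  nb <- find_neighbours(cat_ev, tolerance_xy = 50, tolerance_t = 5)
  rp <- find_repeats(nb, cat_ev, 0.8)
  out <- withr::local_tempdir()
  paths <- generate_csv(nb, rp, cat_ev, out)
  reps <- read.csv(paths[["repeats"]])
  expect_equal(nrow(reps), 3L)
  expect_equal(length(unique(reps$chain_id)), 1L)
  expect_equal(reps$gap_from_previous_frames, c(NA, 5L, 5L))
  sing <- read.csv(paths[["singles"]])
  expect_equal(sort(sing$id), c(4L, 5L))
  nbs <- read.csv(paths[["neighbours"]])
  expect_equal(nrow(nbs), nrow(nb))
  stats <- read.csv(paths[["neighbour_statistics"]])
  expect_equal(stats$event_id[nrow(stats)], "ALL")
})

test_that("empty detections produce header-only CSV files", {
  cat_ev <- catalog_events(array(0L, c(3, 4, 4)), image_stack(array(1, c(3, 4, 4))))
  nb <- find_neighbours(cat_ev, 50, 5)
  rp <- find_repeats(nb, cat_ev, 0.8)
  out <- withr::local_tempdir()
  paths <- generate_csv(nb, rp, cat_ev, out)
  for (p in paths) {
    lines <- readLines(p)
    expect_equal(length(lines), 1L, info = p)
  }
})

test_that("inter-repeat gaps for onsets (10, 30, 55) are (20, 25)", {
  # direct construction through the classifier on co-located events
  lab <- array(0L, c(60, 6, 6))
  lab[11, 2:3, 2:3] <- 1L
  lab[31, 2:3, 2:3] <- 2L
  lab[56, 2:3, 2:3] <- 3L
  cat_ev <- catalog_events(lab, image_stack(array(1, dim(lab))))
  nb <- find_neighbours(cat_ev, tolerance_xy = 5, tolerance_t = 30)
  rp <- find_repeats(nb, cat_ev, 0.8)
  expect_equal(rp$chains$t_onset, c(10L, 30L, 55L))
  expect_equal(rp$chains$gap_from_previous_frames, c(NA, 20L, 25L))
})
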