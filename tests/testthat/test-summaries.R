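# a small catalogue + neighbour set with fully known geometry
simple_pair <- function(sep_px = 100, gap_frames = 4) {
  lab <- array(0L, c(12, 10, 150))
  lab[2, 5, 10] <- 1L
  lab[2 + gap_frames, 5, 10 + sep_px] <- 2L
  cat_ev <- catalog_events(lab, image_stack(array(1, dim(lab))))
  nb <- find_neighbours(cat_ev, tolerance_xy = sep_px, tolerance_t = gap_frames)
  list(catalog = cat_ev, neighbours = nb)
}

test_that("incidence is events per cell per minute", {
  lab <- array(0L, c(40, 40, 40))
  for (i in 1:30) lab[i, i, i] <- i # 30 one-voxel events
  cat_ev <- catalog_events(lab, image_stack(array(1, dim(lab))))
  expect_equal(incidence(cat_ev, n_cells = 10, recording_minutes = 3), 1)
  expect_equal(incidence(cat_ev, n_cells = 15, recording_minutes = 2), 1)
  empty <- catalog_events(array(0L, c(3, 3, 3)), image_stack(array(1, c(3, 3, 3))))
  expect_equal(incidence(empty, 10, 3), 0)
  expect_warning(val <- incidence(cat_ev, NULL, 3), "n_cells")
  expect_true(is.na(val))
})

test_that("propagation speed divides calibrated distance by onset lag", {
  s <- simple_pair(sep_px = 100, gap_frames = 4)
  sp <- propagation_speeds(s$neighbours, pixel_size = 0.586, frame_interval = 0.2)
  # 100 px * 0.586 um/px = 58.6 um over 4 frames * 0.2 s = 0.8 s
  expect_equal(nrow(sp$speeds), 1L) # unordered: one row for the mutual pair
  expect_equal(sp$median, 58.6 / 0.8)
  expect_equal(sp$median, 73.25)
})

test_that("simultaneous pairs and isolated events yield no speeds", {
  s <- simple_pair(sep_px = 40, gap_frames = 0)
  sp <- propagation_speeds(s$neighbours)
  expect_equal(nrow(sp$speeds), 0L)
  expect_true(is.na(sp$median))
  lone <- catalog_events(
    {
      l <- array(0L, c(5, 5, 5))
      l[2, 2, 2] <- 1L
      l
    },
    image_stack(array(1, c(5, 5, 5)))
  )
  nb <- find_neighbours(lone, 50, 5)
  expect_true(is.na(propagation_speeds(nb)$median))
})

test_that("durations and distances follow the calibration", {
  lab <- array(0L, c(30, 60, 60))
  lab[3:12, 5, 5] <- 1L # 10 frames
  lab[20, 10:39, 11:50] <- 2L # extents y=30, x=40 -> diagonal 50
  lab[25, 50, 50] <- 3L # single voxel
  cat_ev <- catalog_events(lab, image_stack(array(1, dim(lab))))
  dd <- durations_and_distances(cat_ev, pixel_size = 0.586, frame_interval = 0.2)
  expect_equal(dd$duration_s[1], 2.0)
  expect_equal(dd$distance_um[2], 50 * 0.586)
  expect_equal(dd$distance_um[2], 29.3)
  expect_equal(dd$distance_um[3], sqrt(2) * 0.586)
})

test_that("only later-onset neighbours count as consequent waves", {
  lab <- array(0L, c(20, 10, 100))
  lab[5, 5, 10] <- 1L # A at t=4
  lab[8, 5, 40] <- 2L # B at t=7, 30 px from A
  lab[10, 5, 60] <- 3L # C at t=9, 50 px from A, 20 from B
  cat_ev <- catalog_events(lab, image_stack(array(1, dim(lab))))
  nb <- find_neighbours(cat_ev, tolerance_xy = 50, tolerance_t = 5)
  nc <- neighbour_counts(nb, cat_ev)
  expect_equal(nc$counts$n_consequent, c(2L, 1L, 0L))
  expect_equal(nc$mean, 1)
  # simultaneous pair contributes to neither side
  s <- simple_pair(sep_px = 40, gap_frames = 0)
  nc0 <- neighbour_counts(s$neighbours, s$catalog)
  expect_equal(nc0$counts$n_consequent, c(0L, 0L))
})

test_that("doubling the frame interval halves speeds and doubles durations", {
  s <- simple_pair()
  sp1 <- propagation_speeds(s$neighbours, frame_interval = 0.2)
  sp2 <- propagation_speeds(s$neighbours, frame_interval = 0.4)
  expect_equal(sp2$median, sp1$median / 2)
  d1 <- durations_and_distances(s$catalog, frame_interval = 0.2)
  d2 <- durations_and_distances(s$catalog, frame_interval = 0.4)
  expect_equal(d2$duration_s, d1$duration_s * 2)
  expect_equal(d2$distance_um, d1$distance_um)
})

test_that("the recording summary assembles every metric coherently", {
  s <- simple_pair(sep_px = 100, gap_frames = 4)
  sm <- summarise_recording(s$catalog, s$neighbours,
    n_cells = 10, recording_minutes = 2
  )
  expect_equal(sm$n_events, 2L)
  expect_equal(sm$incidence_per_cell_min, 2 / 20)
  expect_equal(sm$median_speed_um_s, 73.25)
  expect_equal(sm$median_duration_s, 0.2)
  expect_equal(sm$mean_neighbour_count, 0.5)
  expect_s3_class(glance(sm), "tbl_df")
})

test_that("summary metrics are invariant under relabelling", {
  lab <- array(0L, c(20, 10, 100))
  lab[5, 5, 10] <- 1L
  lab[8, 5, 40] <- 2L
  lab[10, 5, 60] <- 3L
  st <- image_stack(array(1, dim(lab)))
  relab <- array(0L, dim(lab))
  relab[lab == 1L] <- 3L
  relab[lab == 2L] <- 1L
  relab[lab == 3L] <- 2L
  # metrics that do not reference IDs must agree across relabellings
  for (l in list(lab, relab)) {
    cat_ev <- catalog_events(l, st)
    nb <- find_neighbours(cat_ev, 50, 5)
    sm <- summarise_recording(cat_ev, nb, n_cells = 5, recording_minutes = 1)
    if (!exists("ref_sm")) {
      ref_sm <- sm
    } else {
      expect_equal(sm$median_speed_um_s, ref_sm$median_speed_um_s)
      expect_equal(sm$median_duration_s, ref_sm$median_duration_s)
      expect_equal(sm$mean_neighbour_count, ref_sm$mean_neighbour_count)
    }
  }
})
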