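test_that("a constant stack yields an all-background mask", {
  st <- image_stack(array(7, c(10, 6, 6)))
  expect_false(any(extract_events(st)))
})

test_that("grain thresholding reproduces the full-trace mu + k*sigma rule", {
  # single grain: 100 alternating baseline samples and one spike; the
  # decision must use mean/SD of the WHOLE trace, spike included
  fx <- make_boundary_fixtures()$deflections
  for (f in fx) {
    mask <- extract_events(f$stack, grain_size = 1, sd_threshold = 5)
    mu <- mean(f$trace)
    s <- sd(f$trace)
    expected <- f$trace >= mu + 5 * s
    expect_equal(mask[, 1, 1], expected, info = paste("k =", f$k))
    # the spike frame itself flips exactly at the boundary
    expect_equal(mask[101, 1, 1], f$trace[101] >= mu + 5 * s)
  }
  # across the sweep both outcomes must occur (the boundary is inside 3..7)
  spike_hit <- vapply(
    fx,
    function(f) extract_events(f$stack, 1, 5)[101, 1, 1], logical(1)
  )
  expect_true(any(spike_hit) && !all(spike_hit))
})

test_that("grains switch as blocks and partial blocks use actual pixels", {
  # 6x5 frame, grain 4: blocks of 4x4, 4x1, 2x4, 2x1
  set.seed(1)
  dat <- array(rnorm(100 * 6 * 5, 100, 1), c(100, 6, 5))
  dat[50, 1:4, 1:4] <- 200 # spike confined to block (1,1)
  mask <- extract_events(image_stack(pmax(dat, 0)), grain_size = 4, sd_threshold = 5)
  expect_true(all(mask[50, 1:4, 1:4]))
  expect_false(any(mask[50, 1:4, 5])) # partial block (1,2) unaffected
  # manual recomputation for the trailing 2x1 partial block (rows 5:6, col 5)
  dat <- pmax(dat, 0)
  trace <- apply(dat[, 5:6, 5, drop = FALSE], 1, mean)
  expect_equal(
    mask[, 5, 5],
    trace >= mean(trace) + 5 * sd(trace)
  )
  expect_error(extract_events(image_stack(dat), grain_size = 8), "exceeds")
})

test_that("lowering the SD threshold only grows the mask", {
  sc <- example_scene(n_events = 6, seed = 21)
  st <- generate_stack(sc)$stack
  m5 <- extract_events(st, grain_size = 4, sd_threshold = 5)
  m2 <- extract_events(st, grain_size = 4, sd_threshold = 2)
  expect_true(all(m2[m5])) # threshold-2 mask is a superset of threshold-5
  expect_gt(sum(m2), sum(m5))
})

test_that("3D labelling matches the min-propagation oracle, corners included", {
  # two voxels touching only at a corner across consecutive frames
  corner <- array(FALSE, c(3, 3, 3))
  corner[1, 1, 1] <- TRUE
  corner[2, 2, 2] <- TRUE
  expect_equal(max(label_components(corner)), 1L)
  lab <- label_components(corner)
  expect_equal(partition_signature(lab), partition_signature(oracle_label(corner)))

  for (seed in 1:12) {
    mask <- random_mask(c(9L, 11L, 8L), p = 0.18, seed = seed)
    lab <- label_components(mask)
    expect_identical(lab > 0L, mask)
    expect_equal(
      partition_signature(lab),
      partition_signature(oracle_label(mask)),
      info = paste("seed", seed)
    )
    if (max(lab) > 0L) {
      expect_equal(sort(unique(lab[lab > 0])), seq_len(max(lab)))
    }
  }
})

test_that("event IDs follow first-voxel lexicographic order and are stable", {
  mask <- array(FALSE, c(6, 6, 6))
  mask[5, 1, 1] <- TRUE # later frame, low y/x
  mask[1, 5, 5] <- TRUE # first frame
  lab <- label_components(mask)
  expect_equal(lab[1, 5, 5], 1L)
  expect_equal(lab[5, 1, 1], 2L)
  expect_identical(lab, label_components(mask))
})

test_that("watershed splits the dumbbell but conserves foreground voxels", {
  # two bright 3D blobs joined by a thin bridge
  dm <- c(7L, 15L, 31L)
  dat <- array(0, dm)
  for (t in 2:6) {
    for (y in 1:15) {
      for (x in 1:31) {
        d1 <- sqrt((t - 4)^2 + (y - 8)^2 + (x - 8)^2)
        d2 <- sqrt((t - 4)^2 + (y - 8)^2 + (x - 24)^2)
        dat[t, y, x] <- 100 * max(exp(-d1^2 / 8), exp(-d2^2 / 8))
      }
    }
  }
  mask <- dat >= 25
  mask[4, 8, 8:24] <- TRUE # 1-voxel bridge
  st <- image_stack(dat + 1)
  plain <- create_masks(mask, use_watershed = FALSE)
  split <- create_masks(mask, use_watershed = TRUE, intensities = st)
  expect_equal(max(plain), 1L)
  expect_equal(max(split), 2L)
  # conservation: same foreground voxel multiset, every voxel assigned once
  expect_identical(split > 0L, mask)
  expect_identical(plain > 0L, mask)
  # each watershed region is connected
  for (k in 1:2) {
    expect_equal(max(label_components(split == k)), 1L)
  }
})

test_that("cleanup applies the strict below-threshold rule and relabels", {
  fx <- make_boundary_fixtures()$volumes
  out <- cleanup(fx$labels, 40)
  vols <- tabulate(out[out > 0])
  expect_equal(sort(vols), 40:45) # 35..39 removed, 40 retained
  expect_equal(max(out), 6L)
  expect_identical(cleanup(fx$labels, 0), fx$labels)
  expect_equal(max(cleanup(fx$labels, 100)), 0L)
  # survivors keep their relative order
  first_vox <- function(lab, k) which(lab == k)[1]
  expect_true(first_vox(out, 1) < first_vox(out, 6))
})
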