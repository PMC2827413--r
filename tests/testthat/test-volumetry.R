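test_that("noise-free two-population phantoms segment to ground truth", {
  ph <- generate_phantom(phantom_spec(
    shape = c(40, 40, 28), spacing_mm = 1,
    tubers = list(tuber_spec(c(13, 13, 14), c(7, 6, 5), grey_sd = 0),
                  tuber_spec(c(30, 28, 14), c(6, 7, 6), orientation_deg = 45,
                             grey_sd = 0)),
    soil_grey_sd = 0
  ))
  m <- segment_tubers(ph$volume, min_voxels = 1)
  expect_identical(m$labels > 0L, ph$truth$labels > 0L)
  expect_setequal(m$components$voxel_count, ph$truth$volumes$voxel_count)
})

test_that("a degenerate all-pass window selects the whole grid", {
  ph <- sphere_phantom(6, n = 21)
  m <- segment_tubers(ph$volume, lower = 0, upper = 65535, min_voxels = 1)
  expect_equal(nrow(m$components), 1L)
  expect_equal(m$components$voxel_count, 21L^3)
})

test_that("a window excluding everything yields an empty mask, not an error", {
  ph <- sphere_phantom(6, n = 21)
  m <- segment_tubers(ph$volume, lower = 60000, upper = 65535)
  expect_equal(nrow(m$components), 0L)
  expect_true(all(m$labels == 0L))
})

test_that("noisy sphere segments within 3% of the analytic count", {
  # Monte-Carlo over seeds: grey populations 2426/3450 sd 50, default window
  errs <- vapply(1:20, function(s) {
    ph <- sphere_phantom(10, n = 29, grey_sd = 50, seed = s)
    m <- segment_tubers(ph$volume)
    m$components$voxel_count / (4 / 3 * pi * 1000) - 1
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.03)
})

test_that("widening the window never shrinks a component", {
  ph <- sphere_phantom(8, grey_sd = 60, blur_sigma = 1, seed = 5)
  narrow <- segment_tubers(ph$volume, 3000, 3900, min_voxels = 1)
  wide <- segment_tubers(ph$volume, 2938, 3963, min_voxels = 1)
  expect_gte(max(wide$components$voxel_count),
             max(narrow$components$voxel_count))
})

test_that("segmentation is invariant under joint monotone grey transforms", {
  ph <- sphere_phantom(7, grey_sd = 50, seed = 11)
  m1 <- segment_tubers(ph$volume, 2938, 3963, min_voxels = 1)
  shifted <- voxel_volume(2 * ph$volume$grey + 100, ph$volume$spacing_mm)
  m2 <- segment_tubers(shifted, 2 * 2938 + 100, 2 * 3963 + 100, min_voxels = 1)
  expect_identical(m1$labels, m2$labels)
})

test_that("min_voxels removes speckle components", {
  ph <- sphere_phantom(6, n = 25)
  g <- ph$volume$grey
  g[2, 2, 2] <- 3450  # single-voxel speckle
  v <- voxel_volume(g, 1)
  expect_equal(nrow(segment_tubers(v, min_voxels = 2)$components), 1L)
  expect_equal(nrow(segment_tubers(v, min_voxels = 1)$components), 2L)
})

test_that("6- and 26-connectivity differ exactly on diagonal touches", {
  g <- array(0, dim = c(8, 8, 8))
  g[2, 2, 2] <- 3450
  g[3, 3, 3] <- 3450  # diagonal neighbour
  v <- voxel_volume(g, 1)
  expect_equal(nrow(segment_tubers(v, min_voxels = 1, connectivity = 26)$components), 1L)
  expect_equal(nrow(segment_tubers(v, min_voxels = 1, connectivity = 6)$components), 2L)
})

test_that("mask edits add, remove and invert as set operations", {
  ph <- sphere_phantom(6, n = 25)
  m <- segment_tubers(ph$volume)
  # add a 5x5x5 box to an empty region
  empty <- apply_mask_edits(m, mask_edit("remove", "box", lo = c(1, 1, 1),
                                         hi = c(25, 25, 25)))
  expect_equal(nrow(empty$components), 0L)
  box <- apply_mask_edits(empty, mask_edit("add", "box", lo = c(2, 2, 2),
                                           hi = c(6, 6, 6), target_label = 1))
  expect_equal(box$components$voxel_count, 125L)
  # add then remove of the same region restores the original mask
  round_trip <- apply_mask_edits(m, list(
    mask_edit("add", "box", lo = c(18, 18, 18), hi = c(22, 22, 22),
              target_label = 7),
    mask_edit("remove", "box", lo = c(18, 18, 18), hi = c(22, 22, 22))
  ))
  expect_identical(round_trip$labels, m$labels)
  # removing a whole component drops it from the table
  gone <- apply_mask_edits(m, mask_edit("remove", "sphere",
                                        center = c(13, 13, 13), radius = 10))
  expect_false(1L %in% gone$components$label)
  expect_error(apply_mask_edits(m, mask_edit("add", "box", lo = c(1, 1, 1),
                                             hi = c(2, 2, 2),
                                             target_label = 0)),
               "target_label")
})

test_that("volumes follow voxel_count * (spacing/10)^3 exactly", {
  g <- array(0, dim = c(12, 12, 12))
  g[2:11, 2:11, 2:11] <- 3450  # 1000 voxels
  m <- segment_tubers(voxel_volume(g, 1), min_voxels = 1)
  expect_equal(measure_volumes(m)$volume_cm3, 1.0)
  # single voxel at the CT scan resolution of 141 um
  g1 <- array(0, dim = c(8, 8, 8)); g1[4, 4, 4] <- 3450
  m1 <- segment_tubers(voxel_volume(g1, 0.141), min_voxels = 1)
  expect_equal(measure_volumes(m1)$volume_cm3, 0.0141^3)
  expect_equal(measure_volumes(m1)$volume_cm3, 2.803e-6, tolerance = 1e-3)
})

test_that("a radius-20 sphere at 0.5 mm lands within 2% of 4/3 pi cm^3", {
  ph <- sphere_phantom(20, n = 49, spacing_mm = 0.5)
  m <- segment_tubers(ph$volume)
  expect_lt(abs(measure_volumes(m)$volume_cm3 / (4 / 3 * pi) - 1), 0.02)
})

test_that("total measured volume is conserved across components", {
  ph <- generate_phantom(phantom_spec(
    shape = c(40, 24, 24), spacing_mm = 1,
    tubers = list(tuber_spec(c(10, 12, 12), c(5, 5, 5), grey_sd = 0),
                  tuber_spec(c(28, 12, 12), c(6, 5, 4), grey_sd = 0)),
    soil_grey_sd = 0
  ))
  m <- segment_tubers(ph$volume, min_voxels = 1)
  mv <- measure_volumes(m)
  expect_equal(sum(mv$volume_cm3), sum(m$labels > 0) * (1 / 10)^3)
})

test_that("tracking keeps identities stable and starts new ones on appearance", {
  mk_mask <- function(centers) {
    g <- array(0, dim = c(60, 20, 20))
    for (ce in centers) {
      idx <- as.matrix(expand.grid((ce[1] - 2):(ce[1] + 2),
                                   (ce[2] - 2):(ce[2] + 2),
                                   (ce[3] - 2):(ce[3] + 2)))
      g[idx] <- 3450
    }
    segment_tubers(voxel_volume(g, 1), min_voxels = 1)
  }
  m1 <- mk_mask(list(c(10, 10, 10), c(50, 10, 10)))
  # identical masks -> identity matching
  tr <- track_tubers(list(m1, m1))
  expect_equal(tr$tuber_id[tr$time_index == 1], tr$tuber_id[tr$time_index == 2])
  # appearance -> new id at t2
  m2 <- mk_mask(list(c(10, 10, 10), c(50, 10, 10), c(30, 10, 10)))
  tr2 <- track_tubers(list(m1, m2))
  expect_equal(length(unique(tr2$tuber_id)), 3L)
  expect_error(track_tubers(list(m1, m1), max_disp = 0), "max_disp")
  expect_error(track_tubers(list(m1)), "2 time points")
})

test_that("two drifting tubers are tracked without identity swap", {
  # 40 voxels apart, drifting 2 voxels per scan over 4 scans; compare the
  # greedy result with the exhaustive 2-object assignment at each step
  centers_at <- function(t) list(c(10 + 2 * t, 10, 10), c(50 + 2 * t, 10, 10))
  mk_mask <- function(centers) {
    g <- array(0, dim = c(70, 20, 20))
    for (ce in centers) {
      idx <- as.matrix(expand.grid((ce[1] - 2):(ce[1] + 2),
                                   (ce[2] - 2):(ce[2] + 2),
                                   (ce[3] - 2):(ce[3] + 2)))
      g[idx] <- 3450
    }
    segment_tubers(voxel_volume(g, 1), min_voxels = 1)
  }
  masks <- lapply(0:3, function(t) mk_mask(centers_at(t)))
  tr <- track_tubers(masks, max_disp = 10)
  per_tuber <- split(tr$centroid_x, tr$tuber_id)
  expect_equal(length(per_tuber), 2L)
  # each identity moves monotonically right by ~2 voxels per scan (no swap;
  # a swap would jump ~40 voxels, which the exhaustive assignment also rejects)
  for (xs in per_tuber) {
    expect_equal(length(xs), 4L)
    expect_true(all(abs(diff(xs) - 2) < 0.5))
  }
})

test_that("volume validation reproduces identity and scaling fits", {
  v <- c(1, 2.5, 4, 8, 16)
  fit <- validate_volumes(v, v)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$pearson_r, 1)
  fit2 <- validate_volumes(2 * v, v)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$pearson_r, 1)
  expect_error(validate_volumes(v, rep(3, 5)), "variance")
  expect_error(validate_volumes(v[1:2], v[1:2]), "3")
})
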