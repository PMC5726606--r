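grid8 <- vol_grid(c(9, 9, 9), voxel_size = 2)

test_that("streamline-ROI intersection is a point-in-voxel test", {
  roi <- new_volume(grid8, FALSE); roi[5, 5, 5] <- TRUE
  centre <- voxel_to_world(c(4, 4, 4), grid8)
  inside <- rbind(centre, centre + 0.3)
  expect_true(streamline_hits_roi(inside, roi))
  expect_false(streamline_hits_roi(inside + 10, roi))
  # a single interior point touching one ROI voxel is enough
  touch <- rbind(centre - 8, centre, centre + 8)
  expect_true(streamline_hits_roi(touch, roi))
})

test_that("raw termination intensity is the hit fraction", {
  roi <- new_volume(grid8, FALSE); roi[5, 5, 5] <- TRUE
  inroi <- voxel_to_world(c(4, 4, 4), grid8)
  outroi <- voxel_to_world(c(0, 0, 0), grid8)
  mk <- function(n_in, n_out)
    c(replicate(n_in, inroi, simplify = FALSE),
      replicate(n_out, outroi, simplify = FALSE))
  expect_identical(raw_termination_value(mk(100, 900), roi, 1000), 0.1)
  expect_identical(raw_termination_value(mk(0, 50), roi, 50), 0)
  expect_identical(raw_termination_value(mk(50, 0), roi, 50), 1)
  expect_error(raw_termination_value(mk(1, 1), roi, 0), "positive")
})

test_that("termination maps store exact count/proportion pairs at seed voxels", {
  wm <- new_volume(grid8, FALSE); wm[4:6, 4:6, 4:6] <- TRUE
  seeds <- extract_gwi(wm, new_volume(grid8, TRUE))
  hits <- seq_len(seeds$n)
  tm <- termination_map(seeds, hits, 200L, grid8, tract = "t", subject = 1L)
  expect_identical(as.vector(tm$proportion), as.vector(tm$counts) / 200)
  lin <- seeds$indices[, 1] + 9 * (seeds$indices[, 2] + 9 * seeds$indices[, 3]) + 1
  expect_identical(tm$counts[lin], hits)
  expect_false(tm$smoothed)
})

test_that("Gaussian smoothing preserves mass and matches the closed-form kernel", {
  g15 <- vol_grid(c(15, 15, 15), voxel_size = 2)
  vol <- new_volume(g15)
  vol[8, 8, 8] <- 1  # impulse at the grid centre, kernel fully inside
  expect_identical(smooth_map(vol, 0), vol)
  expect_error(smooth_map(vol, -1), ">= 0")
  sm <- smooth_map(vol, fwhm_mm = 5)
  expect_lt(abs(sum(sm) - 1), 1e-6)
  # central weight of the separable discrete kernel, computed independently
  sigma_vox <- 5 / (2 * sqrt(2 * log(2))) / 2
  r <- max(1, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2)); k <- k / sum(k)
  expect_equal(sm[8, 8, 8], k[r + 1]^3, tolerance = 1e-12)
  # an off-centre neighbour follows the same product form
  expect_equal(sm[9, 8, 8], k[r + 2] * k[r + 1]^2, tolerance = 1e-12)
})

test_that("group maps average subjects and ignore subject order", {
  a <- new_volume(grid8); a[2, 2, 2] <- 0.2
  b <- new_volume(grid8); b[2, 2, 2] <- 0.4
  gm <- group_map(list(a, b))
  expect_equal(gm[2, 2, 2], 0.3)
  expect_identical(group_map(list(a, b)), group_map(list(b, a)))
  expect_equal(as.vector(group_map(list(a))), as.vector(a))
  expect_error(group_map(list()), "at least one")
})

test_that("unit rescaling maps the range onto [0, 1] and flags constant maps", {
  v <- new_volume(vol_grid(c(3, 1, 1), 1))
  v[] <- c(2, 4, 6)
  expect_equal(as.vector(rescale_unit(v)), c(0, 0.5, 1))
  u <- new_volume(vol_grid(c(3, 1, 1), 1)); u[] <- c(0, 0.25, 1)
  expect_equal(as.vector(rescale_unit(u)), c(0, 0.25, 1))
  const <- new_volume(grid8, 3)
  expect_warning(out <- rescale_unit(const), "constant")
  expect_true(all(out == 0))
})

test_that("tract ROIs validate emptiness and connectivity", {
  m <- new_volume(grid8, FALSE)
  expect_error(tract_roi("empty", m), "empty")
  m[2:3, 2, 2] <- TRUE
  expect_silent(r <- tract_roi("one", m))
  m[8, 8, 8] <- TRUE
  expect_warning(tract_roi("two", m), "2 connected components")
})

test_that("dice scores agree with direct set arithmetic", {
  a <- new_volume(grid8, FALSE); a[1:4, 1, 1] <- TRUE
  b <- new_volume(grid8, FALSE); b[3:6, 1, 1] <- TRUE
  expect_equal(dice(a, b), 2 * 2 / (4 + 4))
  expect_equal(dice(a, a), 1)
})

test_that("the packaged centroid table lists 7 tracts in both hemispheres", {
  tb <- roi_centroids()
  expect_equal(nrow(tb), 14L)
  expect_setequal(unique(tb$hemisphere), c("left", "right"))
  expect_equal(sum(tb$tract == "AF"), 2L)
  expect_true(all(tb$x[tb$hemisphere == "left"] < 0))
  expect_true(all(tb$x[tb$hemisphere == "right"] > 0))
})
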