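test_that("phantom generation is deterministic and satisfies compartment invariants", {
  ph2 <- generate_phantom(default_spec)
  expect_identical(ph2$wm_mask, template_phantom$wm_mask)
  expect_identical(ph2$orientation, template_phantom$orientation)
  expect_identical(lapply(ph2$domain_maps, as.vector),
                   lapply(template_phantom$domain_maps, as.vector))

  ph <- template_phantom
  expect_false(any(ph$wm_mask != 0 & ph$gm_mask != 0))
  # orientation vectors are unit norm on WM voxels
  nrm <- sqrt(rowSums(ph$orientation^2))
  expect_true(all(abs(nrm[which(ph$wm_mask != 0)] - 1) < 1e-6))
  # every truth-termination voxel lies on the WM external surface
  surf <- brute_surface(ph$wm_mask != 0)
  for (tr in ph$truth_terminations)
    expect_true(all(surf[which(tr != 0)]))
})

test_that("a straight tract along +x yields a constant (1,0,0) orientation field", {
  spec <- phantom_spec(
    tract_geometries = list(list(name = "xline",
                                 control_points = rbind(c(-20, 0, 0), c(20, 0, 0)))),
    dispersion = 0, n_subjects = 1, subject_jitter = 0,
    domain_specs = list(), rng_seed = 1)
  ph <- generate_phantom(spec)
  wm_lin <- which(ph$wm_mask != 0)
  expect_true(length(wm_lin) > 0)
  expect_equal(ph$orientation[wm_lin, ],
               matrix(rep(c(1, 0, 0), each = length(wm_lin)), ncol = 3))
})

test_that("termination patches match a brute-force surface scan within the patch radius", {
  ph <- template_phantom
  spec <- ph$spec
  surf <- brute_surface(ph$wm_mask != 0)
  coords <- grid_coordinates(ph$grid)
  for (k in seq_along(ph$tract_names)) {
    end <- ph$curves[[k]]$points[1, ]
    d <- sqrt(rowSums(sweep(coords, 2, end, "-")^2))
    expected <- as.vector(surf) & d <= spec$patch_radius &
      as.vector(ph$tract_id) == k
    expect_identical(as.vector(ph$truth_terminations[[k]] != 0), expected)
  }
})

test_that("a tract running out of the grid is rejected by name", {
  spec <- phantom_spec(
    tract_geometries = list(list(name = "runaway",
                                 control_points = rbind(c(0, 0, 0), c(0, 60, 0)))),
    domain_specs = list())
  expect_error(generate_phantom(spec), "runaway")
})

test_that("cohorts are reproducible per subject and jitter-0 subjects are identical", {
  spec0 <- phantom_spec(n_subjects = 3, subject_jitter = 0, rng_seed = 3)
  co <- generate_cohort(spec0)
  expect_length(co, 3L)
  expect_identical(co[[1]]$wm_mask, co[[2]]$wm_mask)
  expect_identical(co[[2]]$truth_terminations, co[[3]]$truth_terminations)

  specj <- phantom_spec(n_subjects = 2, subject_jitter = 1, rng_seed = 3)
  coj <- generate_cohort(specj)
  # subjects differ under jitter but remain individually reproducible
  expect_false(identical(coj[[1]]$wm_mask, coj[[2]]$wm_mask))
  expect_identical(generate_phantom(specj, 2L)$wm_mask, coj[[2]]$wm_mask)
  # each subject's truth stays on that subject's own WM surface
  for (s in 1:2) {
    surf <- brute_surface(coj[[s]]$wm_mask != 0)
    for (tr in coj[[s]]$truth_terminations)
      expect_true(all(surf[which(tr != 0)]))
  }
})

test_that("domain maps hit their requested termination overlap", {
  ph <- template_phantom
  patch <- ph$truth_terminations[[1]]
  n_patch <- sum(patch != 0)

  m0 <- generate_domain_map(ph, list(name = "d0", tract = "alpha",
                                     target_overlap = 0, radius = 10))
  expect_equal(sum(m0 & patch), 0L)

  m1 <- generate_domain_map(ph, list(name = "d1", tract = "alpha",
                                     target_overlap = 1, radius = 25))
  expect_equal(sum(m1 & patch), n_patch)

  mh <- generate_domain_map(ph, list(name = "dh", tract = "alpha",
                                     target_overlap = 0.5, radius = 12))
  expect_equal(sum(mh & patch), round(0.5 * n_patch))
  achieved <- sum(mh & patch) / n_patch
  expect_lt(abs(achieved - 0.5), 0.05)

  # maps live on grey matter / interface only
  support <- ph$gm_mask != 0 | ph$surface_mask != 0
  expect_true(all(support[which(mh != 0)]))

  # an overlap no ball can reach reports the maximum achievable
  expect_error(
    generate_domain_map(ph, list(name = "bad", tract = "alpha",
                                 target_overlap = 1, radius = 3)),
    "max achievable")
})
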