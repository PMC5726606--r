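small_grid <- vol_grid(c(4, 4, 1), voxel_size = 2)

# build per-subject volumes from an n_subjects x n_voxels matrix
vols_from_matrix <- function(M, grid = small_grid) {
  lapply(seq_len(nrow(M)), function(s) {
    v <- new_volume(grid)
    v[] <- M[s, ]
    v
  })
}

test_that("exhaustive sign-flip p-values equal brute-force enumeration for n = 5", {
  set.seed(21)
  n <- 5
  M_A <- matrix(rnorm(n * 16, 0.1, 0.3), n)
  M_B <- matrix(rnorm(n * 16, 0.0, 0.3), n)
  mask <- new_volume(small_grid, TRUE)
  res <- paired_permutation_map(vols_from_matrix(M_A), vols_from_matrix(M_B),
                                mask, n_permutations = 5000)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 32L)
  p_oracle <- brute_signflip_fwe(M_A - M_B)
  expect_equal(as.vector(res$p_fwe), p_oracle)
})

test_that("identical map sets and zero-variance voxels are never significant", {
  set.seed(22)
  M <- matrix(rnorm(4 * 16), 4)
  mask <- new_volume(small_grid, TRUE)
  res <- paired_permutation_map(vols_from_matrix(M), vols_from_matrix(M), mask)
  expect_equal(sum(res$significant), 0)
  expect_true(all(res$t == 0))
  # constant nonzero differences are zero-variance: statistic 0 by contract
  M_A <- M + 0.5
  res2 <- paired_permutation_map(vols_from_matrix(M_A), vols_from_matrix(M), mask)
  expect_true(all(res2$t == 0))
  expect_equal(sum(res2$significant), 0)
  expect_error(paired_permutation_map(vols_from_matrix(M[1, , drop = FALSE]),
                                      vols_from_matrix(M[1, , drop = FALSE]),
                                      mask),
               "at least 2")
})

test_that("A>B and B>A are never simultaneously significant (antisymmetry)", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 6
    M_A <- matrix(rnorm(n * 16, 0.2, 0.1), n)
    M_B <- matrix(rnorm(n * 16, 0.0, 0.1), n)
    mask <- new_volume(small_grid, TRUE)
    ab <- paired_permutation_map(vols_from_matrix(M_A), vols_from_matrix(M_B),
                                 mask, m_bonferroni = 1)
    ba <- paired_permutation_map(vols_from_matrix(M_B), vols_from_matrix(M_A),
                                 mask, m_bonferroni = 1)
    expect_equal(sum(ab$significant & ba$significant), 0)
  }
})

test_that("a planted 0.5-vs-0 patch effect is detected with high power", {
  # 12 subjects, patch mean 0.5 vs 0, within-patch noise SD 0.05;
  # alpha 0.05 with the full 42-way Bonferroni correction
  patch <- 1:6
  hits <- 0
  n_rep <- 20
  for (rep in 1:n_rep) {
    set.seed(3000 + rep)
    M_A <- matrix(0, 12, 16)
    M_A[, patch] <- rnorm(12 * length(patch), 0.5, 0.05)
    M_B <- matrix(0, 12, 16)
    mask <- new_volume(small_grid, TRUE)
    res <- paired_permutation_map(vols_from_matrix(M_A), vols_from_matrix(M_B),
                                  mask, alpha = 0.05, m_bonferroni = 42,
                                  n_permutations = 5000)
    if (all(res$significant[patch])) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("evidence maps sum pairwise wins on the 0..T-1 scale", {
  g <- small_grid
  mk_sig <- function(voxels) {
    v <- new_volume(g, FALSE); v[voxels] <- TRUE; v
  }
  others <- paste0("t", 2:7)
  # voxel 1 wins all 6 comparisons; voxel 2 wins exactly 3; voxel 3 none
  results <- lapply(seq_along(others), function(i)
    fake_pairwise("t1", others[i], mk_sig(c(1, if (i <= 3) 2))))
  ev <- evidence_map("t1", results, n_tracts = 7)
  expect_equal(ev[1], 6L)
  expect_equal(ev[2], 3L)
  expect_equal(ev[3], 0L)
  expect_true(all(ev <= 6))
  # the display threshold keeps tracts beating at least half the others
  display_min <- ceiling((7 - 1) / 2)
  expect_equal(display_min, 3)
  expect_true(ev[2] >= display_min)
  expect_error(evidence_map("t1", results[1:4], n_tracts = 7), "expected 6")
})

test_that("evidence ROIs keep the two highest scale values (or the maximum only)", {
  g <- small_grid
  ev <- new_volume(g, 0L)
  ev[] <- rep(0:6, length.out = 16)
  attr(ev, "tract") <- "t1"; attr(ev, "n_tracts") <- 7L
  class(ev) <- c("evidence_map", class(ev))
  roi <- evidence_roi(ev)
  expect_identical(as.vector(roi$mask), as.vector(ev == 5 | ev == 6))
  roi_max <- evidence_roi(ev, rule = "max")
  expect_identical(as.vector(roi_max$mask), as.vector(ev == 6))
  # an all-zero evidence map yields an empty ROI (a tract may have no voxel
  # at the required level of evidence)
  ev0 <- new_volume(g, 0L)
  roi0 <- evidence_roi(ev0, n_tracts = 7)
  expect_false(any(roi0$mask))
  expect_error(evidence_roi(ev0, n_tracts = 2), "at least 3")
})

test_that("ROI subdivision partitions at the coronal plane and z boundary", {
  g <- vol_grid(c(8, 30, 8), voxel_size = 2)  # y spans -29..29 mm
  roi <- new_volume(g, FALSE)
  roi[3:5, 1:25, 3:6] <- TRUE  # spans the y = -27 mm plane
  parts <- subdivide_roi(roi, y_plane_mm = -27, superior_boundary = 0)
  # partition: union equals the ROI and the pieces are pairwise disjoint
  expect_identical(as.vector(parts$ant_inf | parts$ant_sup | parts$post),
                   as.vector(roi != 0))
  expect_equal(sum(parts$ant_inf & parts$ant_sup), 0)
  expect_equal(sum(parts$ant_inf & parts$post), 0)
  expect_equal(sum(parts$ant_sup & parts$post), 0)
  # posterior count matches a direct world-coordinate scan
  w <- voxel_to_world(mask_indices(roi), g)
  expect_equal(sum(parts$post), sum(w[, 2] < -27))
  # a wholly posterior ROI produces two empty anterior parts with a warning
  roi_post <- new_volume(g, FALSE)
  roi_post[3, 2:4, 3] <- TRUE
  expect_warning(p2 <- subdivide_roi(roi_post, y_plane_mm = 50), "empty")
  expect_equal(sum(p2$post), sum(roi_post))
  expect_equal(sum(p2$ant_inf) + sum(p2$ant_sup), 0)
  expect_error(subdivide_roi(new_volume(g, FALSE)), "empty")
})
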