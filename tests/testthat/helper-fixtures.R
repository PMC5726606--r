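# Shared fixtures, all built in code.

# default three-tract template phantom, built once per test run
default_spec <- phantom_spec(n_subjects = 2, rng_seed = 7)
template_phantom <- generate_phantom(default_spec)

# a minimal phantom-like object with a hand-made orientation field, for
# tracking tests with exactly known geometry
field_phantom <- function(wm_mask, directions, grid, dispersion = 0,
                          subject = 0L) {
  v <- prod(grid$shape)
  orient <- matrix(0, v, 3L)
  wm_lin <- which(wm_mask != 0)
  if (is.null(dim(directions)))
    directions <- matrix(directions, length(wm_lin), 3L, byrow = TRUE)
  orient[wm_lin, ] <- directions
  structure(list(grid = grid, wm_mask = with_grid(wm_mask, grid),
                 orientation = orient, dispersion = dispersion,
                 subject = as.integer(subject)),
            class = "phantom")
}

# straight WM corridor along +x: `len_vox` voxels starting at voxel ix0,
# single row in y/z at the grid centre
corridor_phantom <- function(len_vox = 5L, shape = c(12L, 7L, 7L),
                             voxel_size = 2, dispersion = 0, ix0 = 2L) {
  grid <- vol_grid(shape, voxel_size)
  wm <- array(FALSE, shape)
  mid <- (shape[2:3] + 1L) %/% 2L
  wm[(ix0 + 1L):(ix0 + len_vox), mid[1], mid[2]] <- TRUE
  list(phantom = field_phantom(wm, c(1, 0, 0), grid, dispersion),
       seed = c(ix0, mid[1] - 1L, mid[2] - 1L),
       corridor_lin = which(wm), grid = grid)
}

# brute-force 6-neighbour external-surface scan (independent oracle)
brute_surface <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!mask[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (p in nb) {
      outside <- any(p < 1) || p[1] > d[1] || p[2] > d[2] || p[3] > d[3]
      if (outside || !mask[p[1], p[2], p[3]]) { out[i, j, k] <- TRUE; break }
    }
  }
  out
}

# brute-force one-sided sign-flip FWE p-values over all 2^n patterns
# (independent oracle for the permutation test)
brute_signflip_fwe <- function(D) {
  n <- nrow(D)
  tstat <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    if (s < 1e-12) 0 else m / (s / sqrt(n))
  }
  t_obs <- apply(D, 2, tstat)
  maxs <- numeric(2^n)
  for (b in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(b, 2^(0:(n - 1))) > 0, -1, 1)
    maxs[b + 1] <- max(apply(s * D, 2, tstat))
  }
  vapply(t_obs, function(t0) mean(maxs >= t0), 0)
}

# assemble a minimal pairwise_result for evidence-map construction tests
fake_pairwise <- function(a, b, sig_vol) {
  structure(list(pair = c(A = a, B = b), significant = sig_vol),
            class = "pairwise_result")
}
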