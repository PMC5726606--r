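## Termination maps: per seed voxel, the proportion of that seed's
## streamlines intersecting a tract ROI, assigned to the seed voxel.
## Subject maps are smoothed, averaged across subjects, and the group map
## rescaled to [0, 1]; the un-rescaled maps feed the statistics stage.

#' Tract region of interest
#'
#' A binary mask placed in the body of a tract, used to select the
#' streamlines belonging to it.  Warns when the mask has more than one
#' 6-connected component.
#'
#' @param name tract name.
#' @param mask binary volume.
#' @param centroid optional world-mm centroid, for provenance.
#' @param plane optional plane of definition (e.g. `"coronal"`).
#' @return An object of class `tract_roi`.
#' @export
tract_roi <- function(name, mask, centroid = NULL, plane = NULL) {
  if (!any(mask != 0)) stop("tract ROI '", name, "' is empty")
  nc <- n_connected_components(mask != 0)
  if (nc > 1L)
    warning("tract ROI '", name, "' has ", nc, " connected components")
  structure(list(name = name, mask = mask, centroid = centroid, plane = plane),
            class = "tract_roi")
}

## number of 6-connected components of a logical array (BFS over voxels)
n_connected_components <- function(mask) {
  d <- dim(mask)
  lin <- which(mask)
  if (!length(lin)) return(0L)
  remaining <- rep(TRUE, length(mask))
  remaining[-lin] <- FALSE
  strides <- c(1L, d[1], d[1] * d[2])
  comp <- 0L
  while (any(remaining)) {
    comp <- comp + 1L
    queue <- which(remaining)[1]
    remaining[queue] <- FALSE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      v0 <- v - 1L
      i <- v0 %% d[1]; j <- (v0 %/% d[1]) %% d[2]; k <- v0 %/% (d[1] * d[2])
      pos <- c(i, j, k)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        p <- pos[ax] + s
        if (p < 0 || p >= d[ax]) next
        nb <- v + s * strides[ax]
        if (remaining[nb]) { remaining[nb] <- FALSE; queue <- c(queue, nb) }
      }
    }
  }
  comp
}

#' Does a streamline intersect an ROI?
#'
#' True iff any streamline point falls in a nonzero ROI voxel.
#'
#' @param streamline n x 3 matrix of world-mm points.
#' @param roi binary volume or [tract_roi()].
#' @param grid the grid (taken from the ROI volume attribute if absent).
#' @return Logical.
#' @export
streamline_hits_roi <- function(streamline, roi, grid = NULL) {
  mask <- if (inherits(roi, "tract_roi")) roi$mask else roi
  if (is.null(grid)) grid <- vol_grid_of(mask)
  idx <- world_to_voxel(streamline, grid)
  keep <- in_grid(idx, grid)
  if (!any(keep)) return(FALSE)
  any(mask[lin_index(idx[keep, , drop = FALSE], grid$shape)] != 0)
}

#' Raw termination intensity of one seed
#'
#' The proportion of a seed's streamlines that contribute to a tract: the
#' number intersecting the tract ROI over the number launched.  A seed with
#' 1000 of 10,000 streamlines reaching the ROI scores 0.1.
#'
#' @param seed_streamlines a `streamline_set` or list of n x 3 matrices.
#' @param roi binary volume or [tract_roi()].
#' @param n_streamlines number of streamlines launched from the seed.
#' @param grid grid for point binning (from the ROI volume if absent).
#' @return Proportion in \[0, 1\].
#' @export
raw_termination_value <- function(seed_streamlines, roi, n_streamlines,
                                  grid = NULL) {
  if (n_streamlines <= 0) stop("'n_streamlines' must be positive")
  if (inherits(seed_streamlines, "streamline_set"))
    seed_streamlines <- seed_streamlines$streamlines
  hits <- sum(vapply(seed_streamlines, streamline_hits_roi, TRUE,
                     roi = roi, grid = grid))
  hits / n_streamlines
}

#' Build a subject's termination map for one tract
#'
#' Assigns to every seed voxel the proportion of its streamlines that hit
#' the tract ROI.  The integer hit counts are retained alongside the
#' proportions.
#'
#' @param seeds a `seed_set`.
#' @param hit_counts integer vector, per-seed streamline hit counts (one
#'   column of [track_subject()]'s `hits`).
#' @param n_streamlines streamlines launched per seed.
#' @param grid the common grid.
#' @param tract tract name.
#' @param subject subject id.
#' @return An object of class `termination_map` with `proportion` and
#'   `counts` volumes.
#' @export
termination_map <- function(seeds, hit_counts, n_streamlines, grid,
                            tract = "", subject = NA_integer_) {
  stopifnot(length(hit_counts) == seeds$n)
  counts <- new_volume(grid, 0L)
  lin <- lin_index(seeds$indices, grid$shape)
  counts[lin] <- as.integer(hit_counts)
  structure(list(tract = tract, subject = subject,
                 proportion = with_grid(counts / n_streamlines, grid),
                 counts = with_grid(counts, grid),
                 n_streamlines = n_streamlines,
                 smoothed = FALSE, rescaled = FALSE, grid = grid),
            class = "termination_map")
}

#' @export
print.termination_map <- function(x, ...) {
  cat(sprintf(
    "<termination_map> tract '%s' subject %s | %d nonzero voxels | max %.4f%s%s\n",
    x$tract, x$subject, sum(x$proportion != 0), max(x$proportion),
    if (x$smoothed) " | smoothed" else "",
    if (x$rescaled) " | rescaled" else ""))
  invisible(x)
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

shift_zero <- function(a, s, axis) {
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s >= 0) 1:(n - s) else (1 - s):n
  dst <- if (s >= 0) (1 + s):n else 1:(n + s)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  si <- ix; si[[axis]] <- src
  di <- ix; di[[axis]] <- dst
  out[di[[1]], di[[2]], di[[3]]] <- a[si[[1]], si[[2]], si[[3]]]
  out
}

#' Gaussian-smooth a volume
#'
#' Separable discrete Gaussian with SD = FWHM / (2 sqrt(2 ln 2)) per axis
#' in mm (converted to voxels by the voxel size), zero boundary handling,
#' kernel normalised to unit sum.  `fwhm_mm = 0` is the identity.
#'
#' @param x volume or [termination_map()].
#' @param fwhm_mm full width at half maximum, mm.
#' @param grid grid (from the volume attribute if absent).
#' @return Same type as the input; a `termination_map` has both its
#'   `proportion` and `counts` volumes smoothed and `smoothed = TRUE`.
#' @export
smooth_map <- function(x, fwhm_mm = 5, grid = NULL) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (inherits(x, "termination_map")) {
    x$proportion <- smooth_map(x$proportion, fwhm_mm, x$grid)
    x$counts <- smooth_map(x$counts, fwhm_mm, x$grid)
    x$smoothed <- x$smoothed || fwhm_mm > 0
    return(x)
  }
  if (fwhm_mm == 0) return(x)
  if (is.null(grid)) grid <- vol_grid_of(x)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- array(as.numeric(x), dim = grid$shape)
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / grid$voxel_size[ax])
    r <- (length(k) - 1L) / 2L
    acc <- array(0, grid$shape)
    for (j in seq_along(k)) acc <- acc + k[j] * shift_zero(out, j - r - 1L, ax)
    out <- acc
  }
  with_grid(out, grid)
}

#' Average subject maps into a group map
#'
#' @param subject_maps list of volumes (or `termination_map`s, whose
#'   `proportion` volumes are used) on a shared grid.
#' @return The voxelwise mean volume.
#' @export
group_map <- function(subject_maps) {
  if (!length(subject_maps)) stop("need at least one subject map")
  vols <- lapply(subject_maps, function(m)
    if (inherits(m, "termination_map")) m$proportion else m)
  group_average(vols)
}

#' Rescale a map to the unit interval
#'
#' Affine rescale `(v - min) / (max - min)` so the most probable
#' termination point takes value 1 and the least probable 0.  A constant
#' map collapses to all zeros with a warning.
#'
#' @param x volume.
#' @return Rescaled volume.
#' @export
rescale_unit <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant map: rescaling to all zeros")
    return(x * 0)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  g <- attr(x, "grid")
  if (!is.null(g)) out <- with_grid(out, g)
  out
}

#' Dice coefficient between two masks
#'
#' `2|X n Y| / (|X| + |Y|)`; 1 for identical non-empty masks, `NaN` when
#' both are empty.
#'
#' @param x,y binary volumes on the same grid.
#' @return Numeric in \[0, 1\].
#' @export
dice <- function(x, y) {
  check_same_grid(x, y, "masks")
  2 * sum(x != 0 & y != 0) / (sum(x != 0) + sum(y != 0))
}

#' Bundled tract ROI centroid table
#'
#' Returns the packaged table of MNI centroid coordinates (mm) around which
#' each tract ROI is drawn in real-data use, one row per tract and
#' hemisphere.
#'
#' @return data.frame with columns `tract`, `hemisphere`, `x`, `y`, `z`.
#' @export
roi_centroids <- function() {
  utils::read.delim(system.file("extdata", "roi_centroids.tsv",
                                package = "tractterm"))
}
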