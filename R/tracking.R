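#' Tracking parameters
#'
#' Defaults follow the standard probabilistic-tractography protocol: 10,000
#' streamlines per seed voxel, 0.5 mm step, 500 mm length cap, and a 180
#' degree curvature limit over the scale of one voxel (which forbids only
#' exact reversals).
#'
#' @param n_streamlines streamlines launched per seed voxel.
#' @param step_mm propagation step, mm.
#' @param max_length_mm streamline length cap, mm.
#' @param curvature_limit_deg maximum direction change over one voxel of
#'   trailing arc, degrees, in (0, 180].
#' @param rng_seed integer seed for the tracking random stream.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(n_streamlines = 10000L, step_mm = 0.5,
                            max_length_mm = 500, curvature_limit_deg = 180,
                            rng_seed = 1L) {
  if (n_streamlines < 1) stop("'n_streamlines' must be positive")
  if (step_mm <= 0) stop("'step_mm' must be positive")
  if (max_length_mm <= 0) stop("'max_length_mm' must be positive")
  if (curvature_limit_deg <= 0 || curvature_limit_deg > 180)
    stop("'curvature_limit_deg' must be in (0, 180]")
  structure(list(n_streamlines = as.integer(n_streamlines),
                 step_mm = step_mm, max_length_mm = max_length_mm,
                 curvature_limit_deg = curvature_limit_deg,
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

#' @export
print.tracking_params <- function(x, ...) {
  cat(sprintf(
    "<tracking_params> %d streamlines/seed, step %.2f mm, cap %g mm, curvature limit %g deg, seed %d\n",
    x$n_streamlines, x$step_mm, x$max_length_mm, x$curvature_limit_deg,
    x$rng_seed))
  invisible(x)
}

stop_reason_labels <- c("exclusion_mask", "max_length", "curvature")

orient_flat <- function(phantom) {
  ## column-major (voxel, component) -> flat xyz per voxel for C++
  as.numeric(t(phantom$orientation))
}

#' Sample directions from a voxel orientation distribution
#'
#' Draws unit vectors distributed about `mean_dir` with half-normal angular
#' deviation (SD = `dispersion` degrees, rotation axis uniform in the plane
#' perpendicular to `mean_dir`), sign-aligned to `prev_dir` when given
#' (uniform random sign otherwise).
#'
#' @param mean_dir unit 3-vector, the voxel's principal direction.
#' @param prev_dir previous step direction, or `NULL` for a first step.
#' @param dispersion angular SD, degrees.
#' @param n number of draws.
#' @param rng_seed integer seed.
#' @return n x 3 matrix of unit vectors.
#' @export
sample_direction <- function(mean_dir, prev_dir = NULL, dispersion = 0,
                             n = 1L, rng_seed = 1L) {
  mean_dir <- as.numeric(mean_dir)
  if (abs(sqrt(sum(mean_dir^2)) - 1) > 1e-6) stop("'mean_dir' must be a unit vector")
  cpp_sample_directions(as.integer(n), mean_dir,
                        if (is.null(prev_dir)) NULL else as.numeric(prev_dir),
                        dispersion, as.numeric(rng_seed))
}

#' Propagate a single streamline
#'
#' Steps from the centre of the seed voxel through the phantom orientation
#' field until a stopping rule fires.  The first point inside the exclusion
#' mask is retained, so terminations on grey matter are recorded.
#'
#' @param seed_voxel 0-based voxel triple (a WM voxel).
#' @param phantom a [generate_phantom()] result.
#' @param params a [tracking_params()].
#' @param streamline_index which of the seed's streamlines to reproduce
#'   (0-based); with the same spec, params and index the streamline is
#'   bit-identical across calls.
#' @return List with `points` (n x 3 world mm), `reason` (one of
#'   `"exclusion_mask"`, `"max_length"`, `"curvature"`) and `seed_voxel`.
#' @export
propagate_streamline <- function(seed_voxel, phantom, params = tracking_params(),
                                 streamline_index = 0L) {
  g <- phantom$grid
  res <- cpp_track_seed(g$shape, g$voxel_size, g$origin,
                        array(as.integer(phantom$wm_mask != 0), g$shape),
                        orient_flat(phantom), phantom$dispersion,
                        as.integer(seed_voxel), 1L, params$step_mm,
                        params$max_length_mm, params$curvature_limit_deg,
                        as.numeric(params$rng_seed), phantom$subject, TRUE,
                        as.integer(streamline_index))
  list(points = res$streamlines[[1]],
       reason = stop_reason_labels[res$reasons[1]],
       seed_voxel = as.integer(seed_voxel))
}

#' Track all streamlines from one seed voxel
#'
#' Launches `n_streamlines` from the seed voxel centre and returns the
#' seed's connectivity profile (visitation counts; each streamline
#' increments a voxel at most once) together with the streamlines.
#'
#' @inheritParams propagate_streamline
#' @param keep_streamlines return the polylines (memory-heavy for large
#'   `n_streamlines`).
#' @return List with `connectivity` (integer volume), `n_streamlines`,
#'   `seed_voxel`, `reasons` and (optionally) `streamlines`, a
#'   `streamline_set`.
#' @export
track_seed <- function(seed_voxel, phantom, params = tracking_params(),
                       keep_streamlines = TRUE) {
  g <- phantom$grid
  res <- cpp_track_seed(g$shape, g$voxel_size, g$origin,
                        array(as.integer(phantom$wm_mask != 0), g$shape),
                        orient_flat(phantom), phantom$dispersion,
                        as.integer(seed_voxel), params$n_streamlines,
                        params$step_mm, params$max_length_mm,
                        params$curvature_limit_deg,
                        as.numeric(params$rng_seed), phantom$subject,
                        keep_streamlines, 0L)
  out <- list(connectivity = with_grid(array(res$counts, g$shape), g),
              n_streamlines = params$n_streamlines,
              seed_voxel = as.integer(seed_voxel),
              reasons = stop_reason_labels[res$reasons])
  if (keep_streamlines)
    out$streamlines <- structure(
      list(streamlines = res$streamlines,
           seed_voxels = matrix(as.integer(seed_voxel), params$n_streamlines,
                                3L, byrow = TRUE),
           reasons = stop_reason_labels[res$reasons]),
      class = "streamline_set")
  out
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, 0L)
  cat(sprintf("<streamline_set> %d streamlines, %d-%d points\n",
              length(x$streamlines), min(np), max(np)))
  invisible(x)
}

#' Track a whole subject
#'
#' Batch-propagates `n_streamlines` from every seed voxel and accumulates,
#' per seed, the number of streamlines intersecting each tract ROI, plus
#' the subject's global connectivity profile (the voxelwise sum of all
#' per-seed visitation counts).
#'
#' @param phantom a [generate_phantom()] result.
#' @param seeds a `seed_set` from [extract_gwi()].
#' @param rois named list of binary ROI volumes.
#' @param params a [tracking_params()].
#' @return List with `hits` (seeds x ROIs integer matrix), `global`
#'   (integer volume), `seeds` and `n_streamlines`.
#' @export
track_subject <- function(phantom, seeds, rois, params = tracking_params()) {
  g <- phantom$grid
  roi_mat <- vapply(rois, function(r) {
    check_same_grid(r, phantom$wm_mask, "ROI and phantom")
    as.integer(r != 0)
  }, integer(prod(g$shape)))
  if (is.null(dim(roi_mat))) roi_mat <- matrix(roi_mat, ncol = length(rois))
  res <- cpp_track_batch(g$shape, g$voxel_size, g$origin,
                         array(as.integer(phantom$wm_mask != 0), g$shape),
                         orient_flat(phantom), phantom$dispersion,
                         seeds$indices, roi_mat, params$n_streamlines,
                         params$step_mm, params$max_length_mm,
                         params$curvature_limit_deg,
                         as.numeric(params$rng_seed), phantom$subject)
  colnames(res$hits) <- names(rois)
  list(hits = res$hits,
       global = with_grid(array(res$global, g$shape), g),
       seeds = seeds, n_streamlines = params$n_streamlines)
}

#' Sum per-seed connectivity profiles into a global profile
#'
#' @param profiles list of integer volumes on a shared grid.
#' @return Integer volume, the voxelwise sum.
#' @export
global_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  out <- profiles[[1]]
  for (p in profiles[-1]) {
    check_same_grid(out, p, "connectivity profiles")
    out <- out + p
  }
  g <- attr(profiles[[1]], "grid")
  if (!is.null(g)) out <- with_grid(out, g)
  out
}

#' Average volumes across subjects
#'
#' @param volumes list of volumes on a shared grid.
#' @return The voxelwise mean.
#' @export
group_average <- function(volumes) {
  global_profile(volumes) / length(volumes)
}
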