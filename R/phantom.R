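## Synthetic volumetric phantoms: disjoint WM/GM compartments built around
## parametric tract curves, a per-WM-voxel orientation field following the
## curve tangents, ground-truth termination patches on the grey-white
## interface, and binary functional-domain maps with controlled overlap.

#' Specify a synthetic phantom cohort
#'
#' The spec fully determines the cohort: `rng_seed` seeds every random
#' element (inter-subject jitter, and downstream tracking when the spec's
#' seed is reused), so two calls with the same spec are identical.
#'
#' Each tract is a polyline of control points in world mm.  White matter is
#' the tube of voxels within `corridor_radius` of a curve; grey matter is a
#' shell of thickness `gm_thickness` around it.  Each curve end carries a
#' termination patch: the WM-surface voxels of that tract within
#' `patch_radius` of the endpoint.  End 1 of every tract is its "lobe" end:
#' the lobe mask (the analysis region, standing in for a temporal lobe
#' mask) is the union of balls of `lobe_radius` around the lobe-end
#' endpoints.
#'
#' @param grid_shape voxels per axis (default 40 x 48 x 40).
#' @param voxel_size mm (default 2, isotropic).
#' @param n_tracts number of tracts; used only when `tract_geometries` is
#'   `NULL`, in which case a default fan of well-separated straight tracts
#'   is laid out (up to 5).
#' @param tract_geometries list; each element a list with `name` and
#'   `control_points` (k x 3 matrix, world mm; row 1 is the lobe end).
#' @param dispersion angular SD of orientation noise, degrees.
#' @param n_subjects cohort size.
#' @param subject_jitter SD (mm) of the Gaussian displacement applied to
#'   every control point, independently per subject.
#' @param domain_specs list; each element a list with `name`, `tract` (name
#'   or index whose lobe-end termination patch the map should overlap),
#'   `target_overlap` in \[0, 1\], optional `centre` (world mm, default the
#'   patch centroid) and `radius` (mm, default 10).
#' @param rng_seed integer seeding all phantom randomness.
#' @param corridor_radius WM tube radius, mm.
#' @param gm_thickness GM shell thickness, mm.
#' @param patch_radius termination patch radius, mm.
#' @param lobe_radius lobe-mask ball radius, mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 48L, 40L), voxel_size = 2,
                         n_tracts = 3L, tract_geometries = NULL,
                         dispersion = 5, n_subjects = 12L,
                         subject_jitter = 1, domain_specs = NULL,
                         rng_seed = 1L, corridor_radius = 4,
                         gm_thickness = 4, patch_radius = 10,
                         lobe_radius = 10) {
  grid <- vol_grid(grid_shape, voxel_size)
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (n_subjects < 1) stop("'n_subjects' must be >= 1")
  if (subject_jitter < 0) stop("'subject_jitter' must be >= 0")
  if (is.null(tract_geometries))
    tract_geometries <- default_tract_geometries(n_tracts)
  n_tracts <- length(tract_geometries)
  nm <- vapply(tract_geometries, function(t) as.character(t$name), "")
  if (anyDuplicated(nm)) stop("tract names must be unique")
  if (is.null(domain_specs)) domain_specs <- default_domain_specs(nm)
  structure(list(grid = grid, n_tracts = n_tracts,
                 tract_geometries = tract_geometries,
                 dispersion = dispersion, n_subjects = as.integer(n_subjects),
                 subject_jitter = subject_jitter, domain_specs = domain_specs,
                 rng_seed = as.integer(rng_seed),
                 corridor_radius = corridor_radius,
                 gm_thickness = gm_thickness, patch_radius = patch_radius,
                 lobe_radius = lobe_radius),
            class = "phantom_spec")
}

default_tract_geometries <- function(n_tracts) {
  if (n_tracts < 1 || n_tracts > 5)
    stop("default geometries cover 1 to 5 tracts; pass 'tract_geometries'")
  xz <- list(c(-10, -10), c(10, -10), c(0, 15), c(-17, 8), c(17, 8))
  nm <- c("alpha", "beta", "gamma", "delta", "epsilon")
  lapply(seq_len(n_tracts), function(k) {
    list(name = nm[k],
         control_points = rbind(c(xz[[k]][1], -20, xz[[k]][2]),
                                c(xz[[k]][1],   4, xz[[k]][2]),
                                c(xz[[k]][1],  28, xz[[k]][2])))
  })
}

default_domain_specs <- function(tract_names) {
  n <- min(2L, length(tract_names))
  lapply(seq_len(n), function(k)
    list(name = paste0("domain_", tract_names[k]), tract = tract_names[k],
         target_overlap = 0.7, radius = 10))
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s voxels @ %g mm | %d tracts, dispersion %g deg | %d subjects, jitter %g mm | %d domain maps | seed %d\n",
    paste(x$grid$shape, collapse = "x"), x$grid$voxel_size[1], x$n_tracts,
    x$dispersion, x$n_subjects, x$subject_jitter, length(x$domain_specs),
    x$rng_seed))
  invisible(x)
}

## deterministic 31-bit seed derivation (hierarchical streams)
derive_seed <- function(base, ...) {
  x <- as.numeric(base) %% 2147483647
  for (v in c(...)) x <- (x * 69069 + as.numeric(v) * 1234567 + 12345) %% 2147483647
  as.integer(x)
}

## resample a polyline at ~ds spacing; returns points and unit tangents
densify_polyline <- function(cp, ds = 0.5) {
  cp <- rbind3(cp)
  seg <- diff(cp)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate curve (zero length)")
  s <- seq(0, total, by = ds)
  if (s[length(s)] < total) s <- c(s, total)
  pts <- matrix(0, length(s), 3L)
  for (ax in 1:3) pts[, ax] <- stats::approx(cum, cp[, ax], xout = s)$y
  tang <- rbind(pts[2, ] - pts[1, ], (pts[-(1:2), , drop = FALSE] -
                 pts[1:(nrow(pts) - 2), , drop = FALSE]) / 2,
                pts[nrow(pts), ] - pts[nrow(pts) - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  list(points = pts, tangents = tang, length = total)
}

## min distance from every voxel centre to curve samples + index of nearest
curve_distance_field <- function(coords, samples, chunk = 64L) {
  v <- nrow(coords)
  best <- rep(Inf, v)
  arg <- rep(1L, v)
  for (s0 in seq(1L, nrow(samples), by = chunk)) {
    s1 <- min(s0 + chunk - 1L, nrow(samples))
    blk <- samples[s0:s1, , drop = FALSE]
    d2 <- outer(rowSums(coords^2), rep(1, nrow(blk))) -
      2 * coords %*% t(blk) +
      outer(rep(1, v), rowSums(blk^2))
    mi <- max.col(-d2, ties.method = "first")
    mv <- d2[cbind(seq_len(v), mi)]
    upd <- mv < best
    best[upd] <- mv[upd]
    arg[upd] <- s0 - 1L + mi[upd]
  }
  list(dist = sqrt(pmax(best, 0)), arg = arg)
}

#' Generate a phantom
#'
#' Builds one subject's volumes from a [phantom_spec()]: WM/GM compartments,
#' orientation field, lobe mask, per-tract ground-truth termination patches
#' and domain maps.  `subject = 0` is the jitter-free template; subjects
#' `1..n_subjects` apply control-point jitter seeded by
#' `(rng_seed, subject)`, so any subject is reproducible in isolation.
#'
#' @param spec a [phantom_spec()].
#' @param subject subject number (0 = template).
#' @return An object of class `phantom`.
#' @export
generate_phantom <- function(spec, subject = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  geoms <- spec$tract_geometries
  n_t <- length(geoms)
  cps <- lapply(geoms, function(g) rbind3(g$control_points))
  if (subject > 0 && spec$subject_jitter > 0) {
    cps <- local_rng_seed(derive_seed(spec$rng_seed, 7001L, subject), {
      lapply(cps, function(cp)
        cp + matrix(stats::rnorm(length(cp), 0, spec$subject_jitter),
                    nrow(cp), 3L))
    })
  }
  lo <- voxel_to_world(c(0, 0, 0), grid)
  hi <- voxel_to_world(grid$shape - 1L, grid)
  margin <- spec$corridor_radius + spec$gm_thickness
  curves <- vector("list", n_t)
  for (k in seq_len(n_t)) {
    curves[[k]] <- densify_polyline(cps[[k]], ds = min(grid$voxel_size) / 4)
    p <- curves[[k]]$points
    if (any(sweep(p, 2, lo + margin, "<")) || any(sweep(p, 2, hi - margin, ">")))
      stop(sprintf("tract '%s' exits the grid (needs %g mm clearance)",
                   geoms[[k]]$name, margin))
  }
  coords <- grid_coordinates(grid)
  v <- nrow(coords)
  dist <- matrix(Inf, v, n_t)
  args <- matrix(1L, v, n_t)
  for (k in seq_len(n_t)) {
    df <- curve_distance_field(coords, curves[[k]]$points)
    dist[, k] <- df$dist
    args[, k] <- df$arg
  }
  nearest <- max.col(-dist, ties.method = "first")
  mindist <- dist[cbind(seq_len(v), nearest)]
  wm_v <- mindist <= spec$corridor_radius
  n_overlap <- sum(rowSums(dist <= spec$corridor_radius) >= 2)
  gm_v <- !wm_v & mindist <= spec$corridor_radius + spec$gm_thickness
  tract_id <- integer(v)
  tract_id[wm_v] <- nearest[wm_v]
  orient <- matrix(0, v, 3L)
  for (k in seq_len(n_t)) {
    sel <- wm_v & tract_id == k
    orient[sel, ] <- curves[[k]]$tangents[args[sel, k], , drop = FALSE]
  }
  shp <- grid$shape
  as_vol <- function(x) with_grid(array(x, dim = shp), grid)
  wm <- as_vol(wm_v)
  gm <- as_vol(gm_v)
  surf <- mask_surface(wm)
  patches <- vector("list", n_t)
  truth <- vector("list", n_t)
  lobe_v <- rep(FALSE, v)
  for (k in seq_len(n_t)) {
    ends <- curves[[k]]$points[c(1L, nrow(curves[[k]]$points)), , drop = FALSE]
    on_tract <- as.vector(surf) & tract_id == k
    pk <- lapply(1:2, function(e) {
      d <- sqrt(rowSums(sweep(coords, 2, ends[e, ], "-")^2))
      as_vol(on_tract & d <= spec$patch_radius)
    })
    names(pk) <- c("lobe_end", "far_end")
    patches[[k]] <- pk
    truth[[k]] <- pk$lobe_end
    lobe_v <- lobe_v |
      sqrt(rowSums(sweep(coords, 2, ends[1L, ], "-")^2)) <= spec$lobe_radius
  }
  nm <- vapply(geoms, function(g) g$name, "")
  names(patches) <- names(truth) <- nm
  ph <- structure(list(
    grid = grid, spec = spec, subject = as.integer(subject),
    tract_names = nm,
    wm_mask = wm, gm_mask = gm, lobe_mask = as_vol(lobe_v),
    brain_mask = as_vol(wm_v | gm_v),
    surface_mask = surf,
    orientation = orient, dispersion = spec$dispersion,
    tract_id = as_vol(tract_id),
    truth_terminations = truth, termination_patches = patches,
    n_overlapping_corridor_voxels = n_overlap,
    curves = curves, domain_maps = list()), class = "phantom")
  ph$domain_maps <- lapply(spec$domain_specs, function(d) generate_domain_map(ph, d))
  names(ph$domain_maps) <- vapply(spec$domain_specs, function(d) d$name, "")
  ph
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> subject %d | %s voxels | WM %d, GM %d voxels | %d tracts (%s) | %d domain maps\n",
    x$subject, paste(x$grid$shape, collapse = "x"),
    sum(x$wm_mask), sum(x$gm_mask), length(x$tract_names),
    paste(x$tract_names, collapse = ", "), length(x$domain_maps)))
  if (x$n_overlapping_corridor_voxels > 0)
    cat(sprintf("  note: %d voxels lie in more than one tract corridor\n",
                x$n_overlapping_corridor_voxels))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_cohort`: a list of `n_subjects` phantoms; the
#'   jitter-free template is attached as `attr(, "template")`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  subjects <- lapply(seq_len(spec$n_subjects), function(k) generate_phantom(spec, k))
  structure(subjects, template = generate_phantom(spec, 0L),
            class = c("phantom_cohort", "list"))
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects, %d tracts\n",
              length(x), length(attr(x, "template")$tract_names)))
  invisible(x)
}

#' Generate a functional-domain map with controlled termination overlap
#'
#' Builds a binary map supported on grey matter and the grey-white
#' interface: a ball around `centre` intersected with that support, then
#' adjusted so the proportion of the target tract's termination patch it
#' covers equals `target_overlap` (to the nearest voxel).  Patch voxels
#' nearest the centre are included first.
#'
#' @param phantom a [generate_phantom()] result.
#' @param domain_spec list with `name`, `tract`, `target_overlap`, optional
#'   `centre` and `radius` (see [phantom_spec()]).
#' @return Logical volume.
#' @export
generate_domain_map <- function(phantom, domain_spec) {
  stopifnot(inherits(phantom, "phantom"))
  d <- domain_spec
  tr <- if (is.character(d$tract)) match(d$tract, phantom$tract_names) else as.integer(d$tract)
  if (is.na(tr) || tr < 1 || tr > length(phantom$tract_names))
    stop("unknown tract in domain spec: ", d$tract)
  patch <- as.vector(phantom$truth_terminations[[tr]]) != 0
  coords <- grid_coordinates(phantom$grid)
  if (is.null(d$centre)) {
    d$centre <- colMeans(coords[patch, , drop = FALSE])
  }
  if (any(world_to_voxel(d$centre, phantom$grid) < 0) ||
      any(world_to_voxel(d$centre, phantom$grid) >= phantom$grid$shape))
    stop("domain centre outside the grid")
  radius <- if (is.null(d$radius)) 10 else d$radius
  support <- (as.vector(phantom$gm_mask) != 0) | (as.vector(phantom$surface_mask) != 0)
  dc <- sqrt(rowSums(sweep(coords, 2, d$centre, "-")^2))
  ball <- support & dc <= radius
  reachable <- which(patch & ball)
  n_patch <- sum(patch)
  if (n_patch == 0) stop("target tract has an empty termination patch")
  want <- round(d$target_overlap * n_patch)
  if (want > length(reachable))
    stop(sprintf(
      "unreachable target overlap %.2f for domain '%s': max achievable is %.3f (%d of %d patch voxels in support)",
      d$target_overlap, d$name, length(reachable) / n_patch,
      length(reachable), n_patch))
  keep <- reachable[order(dc[reachable])][seq_len(want)]
  mapv <- ball & !patch
  mapv[keep] <- TRUE
  with_grid(array(mapv, dim = phantom$grid$shape), phantom$grid)
}

#' Write a phantom to disk
#'
#' Masks, truth patches and domain maps as NIfTI; orientation field as one
#' NIfTI per component; a JSON manifest listing every file.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @return Manifest path, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wv <- function(vol, name) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    write_volume(vol, p, grid = phantom$grid)
    paths[[name]] <<- p
  }
  wv(phantom$wm_mask, "wm_mask"); wv(phantom$gm_mask, "gm_mask")
  wv(phantom$lobe_mask, "lobe_mask"); wv(phantom$brain_mask, "brain_mask")
  for (k in seq_along(phantom$tract_names))
    wv(phantom$truth_terminations[[k]],
       paste0("truth_", phantom$tract_names[k]))
  for (nmd in names(phantom$domain_maps))
    wv(phantom$domain_maps[[nmd]], nmd)
  for (ax in 1:3)
    wv(with_grid(array(phantom$orientation[, ax], phantom$grid$shape), phantom$grid),
       paste0("orientation_", c("x", "y", "z")[ax]))
  manifest <- list(subject = phantom$subject, tracts = as.list(phantom$tract_names),
                   dispersion_deg = phantom$dispersion, files = paths)
  mp <- file.path(dir, "phantom_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

## evaluate `expr` under a temporary RNG seed, restoring global RNG state
local_rng_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
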