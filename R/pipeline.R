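## End-to-end study driver: phantom cohort -> GWI seeds -> tracking ->
## termination maps -> pairwise evidence -> termination ROIs -> overlap
## matrix, with a manifest making every output traceable to its config.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end study.  All randomness flows from
#' `rng_seed`: the phantom spec and tracking params inherit it unless they
#' carry their own.
#'
#' @param phantom a [phantom_spec()] or a list of arguments for it.
#' @param tracking a [tracking_params()] or a list of arguments for it.
#' @param fwhm_mm Gaussian smoothing FWHM applied to subject maps, mm.
#' @param alpha significance level for both inference stages.
#' @param n_permutations_pairwise permutation budget per pairwise
#'   comparison (exhaustive enumeration is used when `2^n_subjects` is
#'   smaller).
#' @param m_bonferroni Bonferroni divisor for the pairwise maps; default
#'   all ordered tract pairs, `T (T - 1)`.
#' @param use_smoothed run the pairwise statistics on smoothed subject
#'   maps (un-smoothed raw proportions otherwise; both are un-rescaled).
#' @param evidence_rule `"top_two"` or `"max"` for ROI extraction.
#' @param n_permutations_overlap null draws per overlap test.
#' @param m_overlap Bonferroni divisor for the overlap gate; default the
#'   number of matrix cells.
#' @param split_hemispheres test left/right ROI halves separately.
#' @param rng_seed master integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = list(), tracking = list(),
                            fwhm_mm = 5, alpha = 0.05,
                            n_permutations_pairwise = 5000L,
                            m_bonferroni = NULL, use_smoothed = TRUE,
                            evidence_rule = "top_two",
                            n_permutations_overlap = 10000L,
                            m_overlap = NULL, split_hemispheres = FALSE,
                            rng_seed = 1L) {
  if (!inherits(phantom, "phantom_spec")) {
    if (is.null(phantom$rng_seed)) phantom$rng_seed <- rng_seed
    phantom <- do.call(phantom_spec, phantom)
  }
  if (!inherits(tracking, "tracking_params")) {
    if (is.null(tracking$rng_seed)) tracking$rng_seed <- derive_seed(rng_seed, 11L)
    tracking <- do.call(tracking_params, tracking)
  }
  structure(list(phantom = phantom, tracking = tracking, fwhm_mm = fwhm_mm,
                 alpha = alpha,
                 n_permutations_pairwise = as.integer(n_permutations_pairwise),
                 m_bonferroni = m_bonferroni, use_smoothed = use_smoothed,
                 evidence_rule = evidence_rule,
                 n_permutations_overlap = as.integer(n_permutations_overlap),
                 m_overlap = m_overlap,
                 split_hemispheres = split_hemispheres,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so a typo cannot silently fall back to a
#' default.
#'
#' @param path YAML file; top-level keys are the arguments of
#'   [pipeline_config()], with `phantom` and `tracking` as nested maps.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nested in c("phantom", "tracking")) {
    fn <- if (nested == "phantom") phantom_spec else tracking_params
    extra <- setdiff(names(raw[[nested]]), names(formals(fn)))
    if (length(extra))
      stop("unknown ", nested, " config key(s): ", paste(extra, collapse = ", "))
  }
  if (!is.null(raw$phantom$tract_geometries))
    raw$phantom$tract_geometries <- lapply(raw$phantom$tract_geometries, function(g) {
      g$control_points <- do.call(rbind, g$control_points)
      g
    })
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  ph <- config$phantom
  x <- unclass(config)
  x$phantom <- list(
    grid_shape = ph$grid$shape, voxel_size = ph$grid$voxel_size[1],
    tract_geometries = lapply(ph$tract_geometries, function(g)
      list(name = g$name,
           control_points = lapply(seq_len(nrow(g$control_points)),
                                   function(i) as.numeric(g$control_points[i, ])))),
    dispersion = ph$dispersion, n_subjects = ph$n_subjects,
    subject_jitter = ph$subject_jitter, domain_specs = ph$domain_specs,
    rng_seed = ph$rng_seed, corridor_radius = ph$corridor_radius,
    gm_thickness = ph$gm_thickness, patch_radius = ph$patch_radius,
    lobe_radius = ph$lobe_radius)
  x$tracking <- unclass(config$tracking)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Tract ROIs from a phantom
#'
#' Places a one-voxel-thick planar ROI in the body of each tract: the slab
#' of voxels at the tract's arc-length midpoint, perpendicular to the
#' dominant tangent axis, covering the corridor cross-section with a small
#' margin for inter-subject jitter.
#'
#' @param phantom a [generate_phantom()] result (normally the template).
#' @param margin_mm extra radius beyond the WM corridor, mm.
#' @return Named list of [tract_roi()] objects.
#' @export
phantom_tract_rois <- function(phantom, margin_mm = 2) {
  spec <- phantom$spec
  grid <- phantom$grid
  coords <- grid_coordinates(grid)
  out <- list()
  for (k in seq_along(phantom$tract_names)) {
    cv <- phantom$curves[[k]]
    mid <- cv$points[ceiling(nrow(cv$points) / 2), ]
    tang <- cv$tangents[ceiling(nrow(cv$points) / 2), ]
    ax <- which.max(abs(tang))
    mid_vox <- world_to_voxel(mid, grid)[1, ]
    d <- sqrt(rowSums(sweep(coords, 2, mid, "-")^2))
    vox_ax <- world_to_voxel(coords, grid)[, ax]
    slab <- vox_ax == mid_vox[ax] & d <= spec$corridor_radius + margin_mm
    mask <- with_grid(array(slab, grid$shape), grid)
    out[[phantom$tract_names[k]]] <-
      tract_roi(phantom$tract_names[k], mask, centroid = mid,
                plane = c("sagittal", "coronal", "axial")[ax])
  }
  out
}

## linear index of the largest map value over the seed (GWI) mask, where
## termination maps are defined
masked_argmax <- function(vol, mask) {
  sel <- which(mask != 0)
  sel[which.max(vol[sel])]
}

#' Run the full termination-mapping study
#'
#' Executes the pipeline end to end on a synthetic cohort: generates the
#' phantoms, extracts grey-white interface seeds per subject, propagates
#' streamlines, builds smoothed termination maps, averages and rescales
#' the group maps, computes all ordered pairwise sign-flip comparisons and
#' per-tract evidence maps, extracts termination ROIs, and tests their
#' overlap with the phantom's functional-domain maps.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, group maps, evidence
#'   maps, the overlap matrix and a JSON manifest are written there.
#' @param verbose print stage progress.
#' @return An object of class `termination_study`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- config$phantom
  params <- config$tracking
  template <- generate_phantom(spec, 0L)
  rois <- phantom_tract_rois(template)
  roi_masks <- lapply(rois, `[[`, "mask")
  tracts <- template$tract_names
  n_t <- length(tracts)
  grid <- template$grid

  subject_maps <- vector("list", spec$n_subjects)
  seed_masks <- vector("list", spec$n_subjects)
  seed_counts <- integer(spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    ph <- generate_phantom(spec, s)
    seeds <- extract_gwi(ph$wm_mask, ph$lobe_mask)
    say("subject %d: %d seeds, tracking %d streamlines/seed",
        s, seeds$n, params$n_streamlines)
    tr <- track_subject(ph, seeds, roi_masks, params)
    maps <- lapply(seq_len(n_t), function(k) {
      m <- termination_map(seeds, tr$hits[, k], params$n_streamlines, grid,
                           tract = tracts[k], subject = s)
      smooth_map(m, config$fwhm_mm)
    })
    names(maps) <- tracts
    subject_maps[[s]] <- maps
    seed_masks[[s]] <- seeds$mask
    seed_counts[s] <- seeds$n
  }
  ## group GWI analysis mask: majority vote across subjects, so voxels that
  ## are interface only under one subject's jitter do not enter inference
  gwi_count <- Reduce(`+`, lapply(seed_masks, function(m) (m != 0) * 1L))
  mask <- with_grid(array(gwi_count >= spec$n_subjects / 2, grid$shape), grid)

  say("group maps")
  group_raw <- group_rescaled <- list()
  for (k in tracts) {
    group_raw[[k]] <- group_map(lapply(subject_maps, function(m) m[[k]]))
    group_rescaled[[k]] <- rescale_unit(group_raw[[k]])
  }

  m_bonf <- if (is.null(config$m_bonferroni)) n_t * (n_t - 1L) else config$m_bonferroni
  say("pairwise permutation maps (m = %d)", m_bonf)
  stat_maps <- function(k) lapply(subject_maps, function(m) {
    tm <- m[[k]]
    if (config$use_smoothed) tm$proportion else tm$counts / tm$n_streamlines
  })
  pairwise <- list()
  for (a in tracts) for (b in setdiff(tracts, a)) {
    pairwise[[paste(a, b, sep = ">")]] <- paired_permutation_map(
      stat_maps(a), stat_maps(b), mask, alpha = config$alpha,
      n_permutations = config$n_permutations_pairwise,
      m_bonferroni = m_bonf,
      rng_seed = derive_seed(config$rng_seed, 211L, match(a, tracts),
                             match(b, tracts)),
      pair = c(A = a, B = b))
  }

  evidence <- lapply(tracts, function(a)
    evidence_map(a, pairwise[grep(paste0("^", a, ">"), names(pairwise))], n_t))
  names(evidence) <- tracts
  term_rois <- lapply(evidence, evidence_roi, n_tracts = n_t,
                      rule = config$evidence_rule)

  say("overlap tests")
  gm_union <- with_grid(
    array(template$gm_mask != 0 | template$surface_mask != 0, grid$shape), grid)
  nonempty <- Filter(function(r) any(r$mask), term_rois)
  overlap <- NULL
  if (length(nonempty) && length(template$domain_maps)) {
    overlap <- overlap_matrix(
      lapply(nonempty, `[[`, "mask"), template$domain_maps, gm_union,
      alpha = config$alpha, m_tests = config$m_overlap,
      n_permutations = config$n_permutations_overlap,
      rng_seed = derive_seed(config$rng_seed, 307L),
      split_hemispheres = config$split_hemispheres, grid = grid)
  }

  ## cohort-level ground truth: the group interface inside each tract's
  ## termination ball (identical to the template patch when jitter is 0)
  coords <- grid_coordinates(grid)
  group_truth <- lapply(seq_along(tracts), function(k) {
    end <- template$curves[[k]]$points[1L, ]
    d <- sqrt(rowSums(sweep(coords, 2, end, "-")^2))
    with_grid(array(as.vector(mask) & d <= spec$patch_radius, grid$shape), grid)
  })
  names(group_truth) <- tracts
  recovery <- data.frame(
    tract = tracts,
    dice = vapply(tracts, function(k)
      dice(term_rois[[k]]$mask, group_truth[[k]]), 0),
    argmax_in_truth = vapply(tracts, function(k)
      group_truth[[k]][masked_argmax(group_raw[[k]], mask)] != 0, TRUE),
    argmax_in_roi = vapply(tracts, function(k)
      term_rois[[k]]$mask[masked_argmax(group_raw[[k]], mask)] != 0, TRUE),
    row.names = NULL)

  manifest <- list(
    rng_seed = config$rng_seed,
    n_subjects = spec$n_subjects, tracts = as.list(tracts),
    n_streamlines = params$n_streamlines,
    seeds_per_subject = as.list(seed_counts),
    fwhm_mm = config$fwhm_mm, alpha = config$alpha,
    m_bonferroni = m_bonf,
    n_permutations_pairwise = config$n_permutations_pairwise,
    n_permutations_overlap = config$n_permutations_overlap,
    outputs = list())

  study <- structure(list(
    config = config, template = template, rois = rois,
    subject_maps = subject_maps, mask = mask,
    group_raw = group_raw, group_rescaled = group_rescaled,
    pairwise = pairwise, evidence = evidence, term_rois = term_rois,
    group_truth = group_truth,
    overlap = overlap, recovery = recovery, manifest = manifest),
    class = "termination_study")

  if (!is.null(out_dir)) study <- write_study(study, out_dir)
  study
}

#' Write the study outputs to a directory
#'
#' @param study a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return The study with its manifest's `outputs` filled in, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- list()
  for (k in names(study$group_raw)) {
    p1 <- file.path(out_dir, paste0(k, "_group_raw.nii.gz"))
    p2 <- file.path(out_dir, paste0(k, "_group_rescaled.nii.gz"))
    p3 <- file.path(out_dir, paste0(k, "_evidence.nii.gz"))
    write_volume(study$group_raw[[k]], p1)
    write_volume(study$group_rescaled[[k]], p2)
    ev <- study$evidence[[k]]
    write_volume(array(as.integer(ev), dim(ev)), p3, grid = study$template$grid)
    outs[[k]] <- list(group_raw = p1, group_rescaled = p2, evidence = p3)
  }
  if (!is.null(study$overlap)) {
    wp <- write_overlap_matrix(study$overlap,
                               tsv = file.path(out_dir, "overlap_matrix.tsv"),
                               json = file.path(out_dir, "overlap_matrix.json"))
    outs$overlap <- wp
  }
  study$manifest$outputs <- outs
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(study)
}

#' @export
print.termination_study <- function(x, ...) {
  cat(sprintf(
    "<termination_study> %d subjects, %d tracts, %d streamlines/seed\n",
    x$config$phantom$n_subjects, length(x$rois),
    x$config$tracking$n_streamlines))
  cat("ground-truth recovery (Dice of evidence ROI vs truth patch):\n")
  print(x$recovery, row.names = FALSE)
  if (!is.null(x$overlap)) print(x$overlap)
  invisible(x)
}

#' @export
summary.termination_study <- function(object, ...) {
  x <- object
  ev_counts <- vapply(x$evidence, function(e) sum(e > 0), 0L)
  roi_sizes <- vapply(x$term_rois, function(r) sum(r$mask), 0L)
  out <- list(
    n_subjects = x$config$phantom$n_subjects,
    tracts = names(x$rois),
    seeds_per_subject = unlist(x$manifest$seeds_per_subject),
    mask_voxels = sum(x$mask != 0),
    evidence_positive_voxels = ev_counts,
    roi_voxels = roi_sizes,
    recovery = x$recovery,
    overlap = x$overlap)
  class(out) <- "summary.termination_study"
  out
}

#' @export
print.summary.termination_study <- function(x, ...) {
  cat(sprintf("termination study: %d subjects, tracts %s\n", x$n_subjects,
              paste(x$tracts, collapse = ", ")))
  cat(sprintf("seeds per subject: %s (analysis mask %d voxels)\n",
              paste(x$seeds_per_subject, collapse = ", "), x$mask_voxels))
  cat("evidence ROI sizes:", paste(sprintf("%s=%d", names(x$roi_voxels),
                                           x$roi_voxels), collapse = " "), "\n")
  print(x$recovery, row.names = FALSE)
  if (!is.null(x$overlap)) print(x$overlap)
  invisible(x)
}

#' Orthogonal-slice QC image of a volume
#'
#' Draws the three mid-slices (or slices through a given world point) of a
#' volume with `image()`, for quick visual checks.
#'
#' @param vol a volume.
#' @param world optional world point the slices pass through.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the voxel triple sliced at.
#' @export
plot_volume_slices <- function(vol, world = NULL, ...) {
  grid <- vol_grid_of(vol)
  at <- if (is.null(world)) (grid$shape - 1L) %/% 2L
        else world_to_voxel(world, grid)[1, ]
  at <- pmin(pmax(at, 0L), grid$shape - 1L)
  op <- graphics::par(mfrow = c(1, 3), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(vol[at[1] + 1L, , ], main = "sagittal", ...)
  graphics::image(vol[, at[2] + 1L, ], main = "coronal", ...)
  graphics::image(vol[, , at[3] + 1L], main = "axial", ...)
  invisible(at)
}
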