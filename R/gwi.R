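## Grey-white interface extraction: the seed layer for tracking is the set
## of white-matter voxels on the external surface of the WM mask, kept only
## where a lobe mask overlaps them.

neighbour_offsets <- function(connectivity = 6L) {
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

## logical array shifted by s voxels along one axis, FALSE-filled
shift_mask <- function(mask, s, axis) {
  d <- dim(mask)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s >= 0) 1:(n - s) else (1 - s):n
  dst <- if (s >= 0) (1 + s):n else 1:(n + s)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  src_ix <- ix; src_ix[[axis]] <- src
  dst_ix <- ix; dst_ix[[axis]] <- dst
  out[dst_ix[[1]], dst_ix[[2]], dst_ix[[3]]] <-
    mask[src_ix[[1]], src_ix[[2]], src_ix[[3]]]
  out
}

## voxels of `mask` with at least one neighbour outside `mask`
## (voxels beyond the grid boundary count as outside)
mask_surface <- function(mask, connectivity = 6L) {
  mask <- mask != 0
  off <- neighbour_offsets(connectivity)
  interior <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(off))) {
    nb <- mask  # nb[v] = mask[v + offset], FALSE beyond the grid
    for (ax in 1:3) if (off[i, ax] != 0) nb <- shift_mask(nb, -off[i, ax], ax)
    interior <- interior & nb
  }
  mask & !interior
}

#' Extract the grey-white interface seed set
#'
#' The seed set is every white-matter voxel on the external surface of the
#' WM mask (at least one face-adjacent neighbour outside the mask, with the
#' grid boundary counting as outside), intersected with a lobe mask.
#'
#' @param wm_mask binary WM volume.
#' @param lobe_mask binary volume restricting the seeds (e.g. a temporal
#'   lobe mask); `NULL` keeps the whole surface.
#' @param connectivity 6 (face adjacency, default) or 26 for the surface
#'   definition.
#' @return A `seed_set`: list with `indices` (n x 3 matrix of 0-based voxel
#'   indices), `n`, `mask` (indicator volume) and `grid`.
#' @export
extract_gwi <- function(wm_mask, lobe_mask = NULL, connectivity = 6L) {
  grid <- attr(wm_mask, "grid")
  if (!is.null(lobe_mask)) check_same_grid(wm_mask, lobe_mask, "wm_mask and lobe_mask")
  if (!any(wm_mask != 0)) warning("empty white-matter mask: empty seed set")
  surf <- mask_surface(wm_mask, connectivity)
  if (!is.null(lobe_mask)) surf <- surf & (lobe_mask != 0)
  idx <- mask_indices(surf)
  structure(list(indices = idx, n = nrow(idx),
                 mask = if (is.null(grid)) surf else with_grid(surf, grid),
                 grid = grid),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d grey-white interface voxels\n", x$n))
  invisible(x)
}

#' Build the tracking exclusion mask
#'
#' Everything outside the white matter forms the exclusion mask: streamlines
#' stop (and record their final point) on entering it.
#'
#' @param wm_mask binary WM volume.
#' @return Logical volume, the complement of `wm_mask`.
#' @export
build_exclusion_mask <- function(wm_mask) {
  out <- wm_mask == 0
  g <- attr(wm_mask, "grid")
  if (!is.null(g)) out <- with_grid(out, g)
  out
}

#' Export a seed set as TSV
#'
#' Three tab-separated columns `i j k` of 0-based voxel indices.
#'
#' @param seeds a `seed_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seeds_tsv <- function(seeds, path) {
  df <- as.data.frame(seeds$indices)
  names(df) <- c("i", "j", "k")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
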