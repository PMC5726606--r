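#' Define a volumetric sampling grid
#'
#' A grid is the common space for every volume in the pipeline: a 3-D voxel
#' lattice with an isotropic-or-not voxel size (mm) and a diagonal
#' voxel-to-world mapping in RAS orientation.  World coordinates of a voxel
#' refer to its centre.
#'
#' @param shape integer vector of length 3, voxels per axis (all positive).
#' @param voxel_size voxel edge length in mm; scalar or length-3 vector.
#' @param origin world coordinate (mm) of the centre of voxel `(0, 0, 0)`.
#'   Defaults to centring the grid on the world origin, so world planes such
#'   as `y = -27` mm fall inside the volume.
#' @return An object of class `vol_grid` with elements `shape`, `voxel_size`
#'   and `origin`.
#' @examples
#' g <- vol_grid(c(40, 48, 40), voxel_size = 2)
#' voxel_to_world(c(0, 0, 0), g)
#' @export
vol_grid <- function(shape, voxel_size = 2, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape <= 0L))
    stop("'shape' must be 3 positive integers")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("'voxel_size' must be positive")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid> %s voxels, %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Allocate a volume on a grid
#'
#' @param grid a [vol_grid()].
#' @param value fill value.
#' @return An array of dimension `grid$shape` carrying the grid as the
#'   `"grid"` attribute.
#' @export
new_volume <- function(grid, value = 0) {
  stopifnot(inherits(grid, "vol_grid"))
  a <- array(value, dim = grid$shape)
  attr(a, "grid") <- grid
  a
}

#' Recover the grid attached to a volume
#'
#' @param x an array produced by [new_volume()] or [read_volume()].
#' @return The `vol_grid`.
#' @export
vol_grid_of <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) stop("volume carries no grid metadata")
  g
}

with_grid <- function(a, grid) {
  attr(a, "grid") <- grid
  a
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based integer triples; world coordinates are mm.
#' A voxel's world coordinate is its centre; [world_to_voxel()] bins a point
#' to the voxel whose centre is nearest along each axis.
#'
#' @param idx n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @param grid a [vol_grid()].
#' @return n x 3 numeric matrix of world mm ([voxel_to_world()]) or n x 3
#'   integer matrix of 0-based indices ([world_to_voxel()]).
#' @export
voxel_to_world <- function(idx, grid) {
  idx <- rbind3(idx)
  sweep(sweep(idx, 2L, grid$voxel_size, "*"), 2L, grid$origin, "+")
}

#' @rdname voxel_to_world
#' @param world n x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @export
world_to_voxel <- function(world, grid) {
  world <- rbind3(world)
  idx <- sweep(sweep(world, 2L, grid$origin, "-"), 2L, grid$voxel_size, "/")
  storage.mode(idx) <- "double"
  matrix(as.integer(floor(idx + 0.5)), ncol = 3L)
}

rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3L)
  storage.mode(x) <- "double"
  x
}

#' Is a voxel index inside the grid?
#' @inheritParams voxel_to_world
#' @return Logical vector.
#' @export
in_grid <- function(idx, grid) {
  idx <- rbind3(idx)
  idx[, 1] >= 0 & idx[, 1] < grid$shape[1] &
    idx[, 2] >= 0 & idx[, 2] < grid$shape[2] &
    idx[, 3] >= 0 & idx[, 3] < grid$shape[3]
}

#' World coordinates of every voxel centre
#' @param grid a [vol_grid()].
#' @return A `prod(shape)` x 3 matrix ordered like `as.vector(array)`.
#' @export
grid_coordinates <- function(grid) {
  sh <- grid$shape
  idx <- cbind(
    rep.int(seq_len(sh[1]) - 1L, sh[2] * sh[3]),
    rep.int(rep(seq_len(sh[2]) - 1L, each = sh[1]), sh[3]),
    rep(seq_len(sh[3]) - 1L, each = sh[1] * sh[2])
  )
  voxel_to_world(idx, grid)
}

#' All 0-based voxel indices of the nonzero voxels of a mask
#' @param mask logical/numeric 3-D array.
#' @return n x 3 integer matrix of 0-based indices.
#' @export
mask_indices <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  matrix(as.integer(w - 1L), ncol = 3L,
         dimnames = NULL)
}

## linear (1-based) index from 0-based voxel triples
lin_index <- function(idx, shape) {
  idx <- rbind3(idx)
  as.integer(idx[, 1] + shape[1] * (idx[, 2] + shape[2] * idx[, 3]) + 1)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

check_same_grid <- function(a, b, what = "volumes") {
  if (is.null(dim(a)) || is.null(dim(b)) || !identical(dim(a), dim(b)))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  ga <- attr(a, "grid"); gb <- attr(b, "grid")
  if (!is.null(ga) && !is.null(gb) && !same_grid(ga, gb))
    stop(sprintf("grid mismatch between %s: differing voxel size or origin", what))
  invisible(TRUE)
}
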