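#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file into a 3-D array carrying its grid metadata.
#' Only diagonal voxel-to-world mappings are supported (the package works in
#' a single common space); an oblique transform is an error.
#'
#' @param path file path.
#' @param reference optional [vol_grid()] the file must match; a mismatch is
#'   an error naming both grids.
#' @return Array with a `"grid"` attribute.
#' @export
read_volume <- function(path, reference = NULL) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4)
    stop("non-diagonal voxel-to-world mapping in ", path)
  if (any(diag(rot) <= 0))
    stop("voxel-to-world mapping must be RAS with positive scales in ", path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected a 3-D volume in ", path)
  grid <- vol_grid(dim(a), voxel_size = diag(rot), origin = aff[1:3, 4])
  if (!is.null(reference) && !same_grid(grid, reference)) {
    stop(sprintf(
      "grid mismatch: %s has %s voxels at %s mm (origin %s) but reference is %s voxels at %s mm (origin %s)",
      path,
      paste(grid$shape, collapse = "x"), paste(grid$voxel_size, collapse = "x"),
      paste(round(grid$origin, 3), collapse = ","),
      paste(reference$shape, collapse = "x"), paste(reference$voxel_size, collapse = "x"),
      paste(round(reference$origin, 3), collapse = ",")))
  }
  a <- array(as.numeric(a), dim = dim(a))
  with_grid(a, grid)
}

#' Write a volume as NIfTI-1
#'
#' Logical and integer-valued volumes are stored as `int32`, everything else
#' as `float64`, so a write/read round trip is lossless.
#'
#' @param vol 3-D array (grid taken from its attribute unless given).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid optional [vol_grid()] overriding the attached one.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, grid = NULL) {
  if (is.null(grid)) grid <- vol_grid_of(vol)
  a <- array(if (is.logical(vol)) as.integer(vol) else as.vector(vol),
             dim = grid$shape)
  integral <- is.integer(a) ||
    (is.numeric(a) && all(a == round(a)) && max(abs(range(a))) < 2^31 - 1)
  if (integral) storage.mode(a) <- "integer"
  aff <- diag(4)
  diag(aff)[1:3] <- grid$voxel_size
  aff[1:3, 4] <- grid$origin
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (integral) "int32" else "double")
  invisible(path)
}
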