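#' @importFrom RNifti readNifti writeNifti asNifti niftiHeader
NULL

grid_from_nifti <- function(img) {
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  aff <- matrix(as.numeric(aff[1:4, 1:4]), 4, 4)
  volume_grid(shape = dim(img)[1:3], affine = aff)
}

nifti_with_grid <- function(values, grid) {
  img <- RNifti::asNifti(values)
  aff <- structure(grid$affine, code = 2L)
  RNifti::`sform<-`(img, aff)
}

#' Read a displacement field from a NIfTI vector image
#'
#' The file must be a 4-D image with exactly 3 values per voxel (X x Y x Z x 3).
#' Displacements follow the pull-from-reference convention `x = X + u(X)`.
#' NIfTI has no standard for whether vector values are physical (mm) or voxel
#' offsets, so the caller declares the file's convention with `units`; voxel
#' offsets are converted to mm through the linear part of the affine.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param mask optional logical array, or path to a mask volume on the same
#'   grid; defaults to all voxels.
#' @param units `"mm"` (default) if stored values are physical displacements,
#'   `"voxel"` if they are voxel-index offsets.
#' @return a [displacement_field()].
#' @export
read_displacement_field <- function(path, mask = NULL, units = c("mm", "voxel")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L) {
    stop(sprintf("displacement field must be X x Y x Z x 3; got dim (%s)",
                 paste(d, collapse = ",")))
  }
  grid <- grid_from_nifti(img)
  u <- array(as.numeric(img), d)
  if (units == "voxel") {
    lin <- grid$affine[1:3, 1:3]
    n <- prod(d[1:3])
    u <- array(matrix(u, n, 3) %*% t(lin), d)
  }
  if (is.character(mask)) mask <- read_mask(mask, grid)
  mask <- check_mask(mask, grid)
  nbad <- sum(!is.finite(u[rep_mask(mask, 3L)]))
  if (nbad > 0) {
    stop(sprintf("%s: %d non-finite displacement components inside the mask", path, nbad))
  }
  displacement_field(u, grid, mask)
}

#' Write a displacement field to NIfTI
#'
#' Values are written in mm. The mask is not stored in the file; write it
#' separately with [write_mask()].
#'
#' @param field a [displacement_field()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  RNifti::writeNifti(nifti_with_grid(field$u, field$grid), path)
  invisible(path)
}

#' Read / write scalar maps
#'
#' @param path NIfTI file with one value per voxel.
#' @param mask optional logical array or mask path.
#' @param name optional parameter name attached to the map.
#' @return a [scalar_map()].
#' @export
read_scalar_map <- function(path, mask = NULL, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- array(as.numeric(img), d[1:3]); d <- d[1:3] }
  if (length(d) != 3L) stop("scalar map must be a 3-D volume")
  grid <- grid_from_nifti(img)
  if (is.character(mask)) mask <- read_mask(mask, grid)
  scalar_map(array(as.numeric(img), d), grid, mask, name = name)
}

#' @rdname read_scalar_map
#' @param map a [scalar_map()].
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  RNifti::writeNifti(nifti_with_grid(map$values, map$grid), path)
  invisible(path)
}

#' Read / write symmetric tensor maps
#'
#' Tensor maps are stored as X x Y x Z x 6 NIfTI volumes with component order
#' xx, yy, zz, xy, yz, zx (see [TENSOR_COMPONENTS]); the order is recorded in
#' the NIfTI description field.
#'
#' @param path NIfTI file.
#' @param mask optional logical array or mask path.
#' @param name optional parameter name.
#' @return a [tensor_map()].
#' @export
read_tensor_map <- function(path, mask = NULL, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 6L) stop("tensor map must be X x Y x Z x 6")
  grid <- grid_from_nifti(img)
  if (is.character(mask)) mask <- read_mask(mask, grid)
  tensor_map(array(as.numeric(img), d), grid, mask, name = name)
}

#' @rdname read_tensor_map
#' @param map a [tensor_map()].
#' @export
write_tensor_map <- function(map, path) {
  stopifnot(inherits(map, "tensor_map"))
  img <- nifti_with_grid(map$values, map$grid)
  img <- RNifti::asNifti(img, list(descrip = paste("sym3x3 order", paste(TENSOR_COMPONENTS, collapse = ","))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a binary mask volume
#'
#' @param path NIfTI file; nonzero voxels are in-mask.
#' @param grid optional grid the mask must match.
#' @return logical array.
#' @export
read_mask <- function(path, grid = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  mgrid <- grid_from_nifti(img)
  if (!is.null(grid)) stop_if_grid_mismatch(grid, mgrid, "mask and volume")
  array(as.numeric(img) != 0, dim(img)[1:3])
}

#' @rdname read_mask
#' @param mask logical array.
#' @export
write_mask <- function(mask, grid, path) {
  RNifti::writeNifti(nifti_with_grid(array(as.integer(mask), grid$shape), grid), path)
  invisible(path)
}

#' Read a label atlas and its names table
#'
#' @param path NIfTI volume of non-negative integer labels (0 = background).
#' @param names_path CSV with columns `label`, `name`; every nonzero label
#'   used in the volume must appear.
#' @return a [label_atlas()].
#' @export
read_label_atlas <- function(path, names_path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("label atlas must be a 3-D volume")
  grid <- grid_from_nifti(img)
  vals <- as.numeric(img)
  if (max(abs(vals - round(vals))) > 1e-6) stop("label atlas is not integer-valued")
  tab <- utils::read.csv(names_path, stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% names(tab))) {
    stop("names file must have columns 'label' and 'name'")
  }
  nm <- stats::setNames(as.character(tab$name), as.character(as.integer(tab$label)))
  label_atlas(array(round(vals), grid$shape), grid, nm)
}

#' @rdname read_label_atlas
#' @param atlas a [label_atlas()].
#' @param names_path where to write the label names CSV.
#' @export
write_label_atlas <- function(atlas, path, names_path = NULL) {
  stopifnot(inherits(atlas, "label_atlas"))
  RNifti::writeNifti(nifti_with_grid(array(as.numeric(atlas$labels), atlas$grid$shape),
                                     atlas$grid), path)
  if (!is.null(names_path)) {
    utils::write.csv(data.frame(label = as.integer(names(atlas$names)),
                                name = unname(atlas$names)),
                     names_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write cohort and results tables (CSV)
#'
#' @param path CSV file.
#' @return for `read_cohort_table`, a validated [cohort_table()].
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_table
#' @param df a data.frame (cohort or results table); written with a header row.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
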