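#' Tensor component storage order
#'
#' Symmetric 3x3 tensors (Lagrange strain) are stored as 6 unique components
#' per voxel in the fixed order xx, yy, zz, xy, yz, zx. This order is used
#' everywhere in the package and recorded in file metadata.
#' @export
TENSOR_COMPONENTS <- c("xx", "yy", "zz", "xy", "yz", "zx")

#' Displacement field on a voxel grid
#'
#' Holds a 3-vector displacement `u(X)` per voxel, in mm, with the
#' pull-from-reference convention `x = X + u(X)`: `X` is the voxel's physical
#' position in the undeformed (earlier-time) configuration and `x` its
#' position in the deformed configuration.
#'
#' @param u numeric array of dim `c(shape, 3)`, displacements in mm.
#' @param grid a [volume_grid()].
#' @param mask logical array of dim `shape`, or `NULL` for all voxels.
#' @return object of class `displacement_field` with fields `grid`, `u`, `mask`.
#' @export
displacement_field <- function(u, grid, mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  u <- as_numeric_array(u, c(grid$shape, 3L), "u")
  mask <- check_mask(mask, grid)
  bad <- !is.finite(u[rep_mask(mask, 3L)])
  if (any(bad)) {
    stop(sprintf("displacement field has %d non-finite component values inside the mask",
                 sum(bad)))
  }
  structure(list(grid = grid, u = u, mask = mask), class = "displacement_field")
}

#' Scalar map on a voxel grid
#'
#' @param values numeric array of dim `shape`.
#' @param grid a [volume_grid()].
#' @param mask logical array or `NULL` (all voxels).
#' @param name optional parameter name (e.g. "jd", "E_xx").
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(values, grid, mask = NULL, name = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  values <- as_numeric_array(values, grid$shape, "values")
  mask <- check_mask(mask, grid, require_nonempty = FALSE)
  structure(list(grid = grid, values = values, mask = mask, name = name),
            class = "scalar_map")
}

#' Symmetric tensor map on a voxel grid
#'
#' Stores one symmetric 3x3 tensor per voxel as 6 unique components in the
#' order given by [TENSOR_COMPONENTS] (xx, yy, zz, xy, yz, zx).
#'
#' @param values numeric array of dim `c(shape, 6)`.
#' @inheritParams scalar_map
#' @return object of class `tensor_map`.
#' @export
tensor_map <- function(values, grid, mask = NULL, name = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  values <- as_numeric_array(values, c(grid$shape, 6L), "values")
  mask <- check_mask(mask, grid, require_nonempty = FALSE)
  structure(list(grid = grid, values = values, mask = mask, name = name),
            class = "tensor_map")
}

#' Reconstruct full symmetric 3x3 tensors from a tensor map
#'
#' @param map a [tensor_map()].
#' @param flat if `TRUE` return an n-voxel x 6 matrix instead of the
#'   `c(shape, 3, 3)` array.
#' @return array of dim `c(shape, 3, 3)` (exactly symmetric) or a matrix.
#' @export
tensor_as_matrix <- function(map, flat = FALSE) {
  stopifnot(inherits(map, "tensor_map"))
  n <- prod(map$grid$shape)
  v <- matrix(map$values, n, 6)
  if (flat) return(v)
  full <- array(0, c(n, 3, 3))
  full[, 1, 1] <- v[, 1]; full[, 2, 2] <- v[, 2]; full[, 3, 3] <- v[, 3]
  full[, 1, 2] <- v[, 4]; full[, 2, 1] <- v[, 4]
  full[, 2, 3] <- v[, 5]; full[, 3, 2] <- v[, 5]
  full[, 3, 1] <- v[, 6]; full[, 1, 3] <- v[, 6]
  array(full, c(map$grid$shape, 3, 3))
}

#' Integer-labelled region atlas
#'
#' @param labels integer array of dim `shape`; 0 is background.
#' @param grid a [volume_grid()].
#' @param names named character vector mapping label id (as name) to region
#'   name; every nonzero label present in `labels` must be named.
#' @return object of class `label_atlas`.
#' @export
label_atlas <- function(labels, grid, names) {
  stopifnot(inherits(grid, "volume_grid"))
  labels <- as_numeric_array(labels, grid$shape, "labels")
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("atlas labels must be non-negative integers")
  }
  labels <- array(as.integer(round(labels)), grid$shape)
  used <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(as.character(used), names(names))
  if (length(missing)) {
    stop(sprintf("atlas labels without a name: %s", paste(missing, collapse = ", ")))
  }
  structure(list(grid = grid, labels = labels,
                 names = names[as.character(used)]),
            class = "label_atlas")
}

#' Validate a longitudinal cohort table
#'
#' One row per (subject, interval) with the inter-scan interval length and the
#' age at the midpoint of the interval. Interval lengths are used for the
#' per-90-day normalisation; midpoint age is the fixed-effect regressor of the
#' mixed model.
#'
#' @param df data.frame with columns `subject_id`, `interval_id`,
#'   `days_between_scans` (positive), `midpoint_age_days` (positive).
#' @return the validated data.frame, classed `cohort_table`.
#' @export
cohort_table <- function(df) {
  req <- c("subject_id", "interval_id", "days_between_scans", "midpoint_age_days")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("cohort table missing columns: %s", paste(miss, collapse = ", ")))
  if (any(df$days_between_scans <= 0)) stop("days_between_scans must be > 0")
  if (any(df$midpoint_age_days <= 0)) stop("midpoint_age_days must be > 0")
  key <- paste(df$subject_id, df$interval_id, sep = "\r")
  if (anyDuplicated(key)) stop("cohort table has duplicated (subject, interval) rows")
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

# ---- internal helpers -------------------------------------------------------

as_numeric_array <- function(x, dims, what) {
  if (is.null(dim(x)) && length(x) == prod(dims)) dim(x) <- dims
  if (!identical(as.integer(dim(x)), as.integer(dims))) {
    stop(sprintf("%s must have dim (%s), got (%s)", what,
                 paste(dims, collapse = ","), paste(dim(x), collapse = ",")))
  }
  storage.mode(x) <- "double"
  x
}

check_mask <- function(mask, grid, require_nonempty = TRUE) {
  if (is.null(mask)) {
    mask <- array(TRUE, grid$shape)
  } else {
    if (!identical(as.integer(dim(mask)), grid$shape)) {
      stop("mask shape does not match grid")
    }
    mask <- array(as.logical(mask), grid$shape)
    mask[is.na(mask)] <- FALSE
  }
  if (require_nonempty && !any(mask)) stop("mask is empty")
  mask
}

# replicate a 3-D logical mask along a trailing component axis
rep_mask <- function(mask, k) {
  array(rep(as.vector(mask), k), c(dim(mask), k))
}

map_values_in_mask <- function(map) {
  map$values[map$mask]
}
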