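#' Regular voxel grid with physical coordinates
#'
#' A `volume_grid` describes the sampling lattice every volumetric object in
#' the package lives on: the number of voxels per axis, the voxel spacing in
#' millimetres, and the affine mapping 0-based voxel indices to physical
#' (RAS, mm) coordinates. All spatial derivatives are taken in the physical
#' frame, so the grid is the single place where units are pinned down.
#'
#' @param shape integer triple, voxels per axis.
#' @param spacing positive real triple, mm per voxel along x, y, z.
#' @param origin physical coordinate (mm) of voxel index (0, 0, 0). Ignored
#'   when `affine` is given.
#' @param affine optional 4x4 affine (voxel index -> mm). Defaults to
#'   `diag(spacing)` with translation `origin`.
#' @return an object of class `volume_grid` with fields `shape`, `spacing`,
#'   `affine`.
#' @export
volume_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    stopifnot(length(spacing) == 3L)
    if (any(spacing <= 0)) stop("all spacing components must be > 0")
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- as.numeric(origin)
  } else {
    stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(spacing <= 0)) stop("affine has a zero-length column; spacing must be > 0")
  }
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels, spacing %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

# TRUE when the linear part of the affine is diagonal with positive entries
# (axis-aligned RAS). Strain derivatives assume this.
grid_is_axis_aligned <- function(grid, tol = 1e-6) {
  lin <- grid$affine[1:3, 1:3]
  off <- lin - diag(diag(lin))
  all(abs(off) <= tol * max(abs(lin))) && all(diag(lin) > 0)
}

#' Check that two grids agree
#'
#' Grids are compatible when shapes match exactly and affines agree within a
#' relative tolerance of 1e-4 on each entry. Operations combining volumes
#' refuse incompatible grids.
#'
#' @param a,b `volume_grid` objects.
#' @param tol relative tolerance on affine entries.
#' @return logical scalar.
#' @export
grids_compatible <- function(a, b, tol = 1e-4) {
  if (!identical(a$shape, b$shape)) return(FALSE)
  scale <- max(abs(a$affine), abs(b$affine), 1)
  all(abs(a$affine - b$affine) <= tol * scale)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_compatible(a, b)) {
    stop(sprintf("%s are on different grids (shape %s vs %s, or affines differ beyond tolerance)",
                 what, paste(a$shape, collapse = "x"), paste(b$shape, collapse = "x")))
  }
  invisible(TRUE)
}

# Physical coordinates (n x 3 mm) of all voxel centres, voxel indices 0-based,
# fastest along x (column-major order matching R arrays).
grid_coordinates <- function(grid) {
  sh <- grid$shape
  ii <- rep.int(seq_len(sh[1]) - 1L, sh[2] * sh[3])
  jj <- rep.int(rep(seq_len(sh[2]) - 1L, each = sh[1]), sh[3])
  kk <- rep(seq_len(sh[3]) - 1L, each = sh[1] * sh[2])
  idx <- cbind(ii, jj, kk)
  xyz <- idx %*% t(grid$affine[1:3, 1:3])
  sweep(xyz, 2, grid$affine[1:3, 4], "+")
}

# mm coordinates -> 0-based fractional voxel indices
world_to_voxel <- function(grid, xyz) {
  inv <- solve(grid$affine)
  out <- xyz %*% t(inv[1:3, 1:3])
  sweep(out, 2, inv[1:3, 4], "+")
}
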