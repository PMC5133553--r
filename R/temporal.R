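#' Normalise a growth-parameter map to a common 90-day interval
#'
#' Scan intervals differ between subjects, so per-interval growth parameters
#' are rescaled to represent change over 90 days (one 3-month period):
#' values are multiplied by `90 / days_between_scans`. Quantities whose null
#' value is not zero (the Jacobian determinant, null JD = 1) are adjusted in
#' offset form by default, `JD_adj = null + (JD - null) * 90/days`, which
#' preserves the null exactly; `mode = "direct"` rescales the raw values
#' instead. The adjustment is recorded in the map's metadata and applying it
#' twice is an error.
#'
#' @param map a [scalar_map()] or [tensor_map()].
#' @param days_between_scans positive number of days between the two scans.
#' @param null_value the parameter's no-growth value (0 for strains and
#'   angles, 1 for JD).
#' @param mode `"offset"` (default: scale the deviation from `null_value`) or
#'   `"direct"` (scale raw values).
#' @param target_days interval length the values are normalised to (90).
#' @return the adjusted map, with attribute `adjustment`.
#' @export
interval_adjust <- function(map, days_between_scans, null_value = 0,
                            mode = c("offset", "direct"), target_days = 90) {
  mode <- match.arg(mode)
  if (!inherits(map, "scalar_map") && !inherits(map, "tensor_map")) {
    stop("interval_adjust expects a scalar_map or tensor_map")
  }
  if (!is.null(attr(map, "adjustment"))) {
    stop("map is already interval-adjusted; refusing to adjust twice")
  }
  if (length(days_between_scans) != 1L || !is.finite(days_between_scans) ||
      days_between_scans <= 0) {
    stop("days_between_scans must be a single positive number")
  }
  f <- target_days / days_between_scans
  if (mode == "offset") {
    map$values <- null_value + (map$values - null_value) * f
  } else {
    map$values <- map$values * f
  }
  attr(map, "adjustment") <- list(kind = "per-90-day", factor = f,
                                  days_between_scans = days_between_scans,
                                  null_value = null_value, mode = mode)
  map
}

#' Resample a map through a deformation field
#'
#' Pulls `map` onto `target_grid`: for each target voxel at physical position
#' `X`, the deformation gives the source-space position `x = X + u(X)` and the
#' map is interpolated there. Scalar and tensor maps use trilinear
#' interpolation of each component (`"linear"`); label volumes should use
#' `"nearest"`. Tensor components are resampled componentwise without
#' reorientation. Voxels sampling outside the source field of view (or
#' outside the source mask for nearest) become missing and leave the output
#' mask.
#'
#' @param map a [scalar_map()] or [tensor_map()].
#' @param deformation a [displacement_field()] defined on the target grid,
#'   mapping target positions to source positions.
#' @param target_grid grid of the output; defaults to the deformation's grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return resampled map of the same class on `target_grid`.
#' @export
warp_map <- function(map, deformation, target_grid = deformation$grid,
                     interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(deformation, "displacement_field"))
  stop_if_grid_mismatch(deformation$grid, target_grid, "deformation and target grid")
  is_tensor <- inherits(map, "tensor_map")
  if (!is_tensor && !inherits(map, "scalar_map")) {
    stop("warp_map expects a scalar_map or tensor_map")
  }
  n <- prod(target_grid$shape)
  X <- grid_coordinates(target_grid)
  x_src <- X + matrix(deformation$u, n, 3)
  vox <- world_to_voxel(map$grid, x_src)        # 0-based fractional indices
  ncomp <- if (is_tensor) 6L else 1L
  src_vals <- matrix(map$values, prod(map$grid$shape), ncomp)
  res <- interp_volume(src_vals, map$grid$shape, vox, interpolation)
  out_mask <- array(res$inside, target_grid$shape) & deformation$mask
  vals <- res$values
  if (is_tensor) {
    tensor_map(array(vals, c(target_grid$shape, 6L)), target_grid, out_mask,
               name = map$name)
  } else {
    scalar_map(array(vals[, 1], target_grid$shape), target_grid, out_mask,
               name = map$name)
  }
}

#' One pass of edge-preserving smoothing
#'
#' Applies `iterations` passes of a 6-neighbour anisotropic-diffusion step
#' (Perona-Malik type): each voxel moves towards its in-mask neighbours with
#' weights `exp(-(d/kappa)^2)` on the intensity difference `d`, step 1/6 per
#' neighbour, so strong edges diffuse much less than smooth gradients. The
#' flux between a voxel pair is antisymmetric, so the in-mask total (and the
#' mean over interior masks) is conserved; constant maps are fixed points and
#' no new extrema are created.
#'
#' @param map a [scalar_map()] (tensor maps: smooth each component map).
#' @param iterations number of diffusion passes (the pipeline default is 1,
#'   "minimal smoothing").
#' @param kappa edge threshold in map units; differences well above `kappa`
#'   are treated as edges and preserved. Default: 90th percentile of the
#'   absolute in-mask neighbour differences (per call).
#' @return smoothed [scalar_map()].
#' @export
smooth_map <- function(map, iterations = 1, kappa = NULL) {
  stopifnot(inherits(map, "scalar_map"))
  v <- map$values
  mask <- map$mask
  m <- array(as.numeric(mask), dim(mask))
  for (it in seq_len(iterations)) {
    if (is.null(kappa)) {
      diffs <- c()
      for (ax in 1:3) {
        nb <- shift_numeric(v, ax, +1L)
        nbm <- shift_numeric(m, ax, +1L, fill = 0)
        ok <- mask & (nbm != 0)
        if (any(ok)) diffs <- c(diffs, abs(nb[ok] - v[ok]))
      }
      diffs <- diffs[is.finite(diffs) & diffs > 0]
      k <- if (length(diffs)) stats::quantile(diffs, 0.9, names = FALSE) else 0
    } else {
      k <- kappa
    }
    if (!is.finite(k) || k <= 0) break   # flat map: nothing to diffuse
    acc <- array(0, dim(v))
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift_numeric(v, ax, s)
      nbm <- shift_numeric(m, ax, s, fill = 0)
      d <- nb - v
      w <- exp(-(d / k)^2)
      flux <- w * d
      flux[!mask | nbm == 0 | !is.finite(flux)] <- 0
      acc <- acc + flux
    }
    v <- v + acc / 6
  }
  scalar_map(v, map$grid, mask, name = map$name)
}

# ---- internal interpolation -------------------------------------------------

# src_vals: (#src voxels) x ncomp matrix (column-major volume order);
# vox: n x 3 fractional 0-based voxel coordinates in the source grid.
interp_volume <- function(src_vals, src_shape, vox, interpolation) {
  n <- nrow(vox)
  ncomp <- ncol(src_vals)
  values <- matrix(NA_real_, n, ncomp)
  if (interpolation == "nearest") {
    idx <- round(vox)
    inside <- idx[, 1] >= 0 & idx[, 1] <= src_shape[1] - 1 &
              idx[, 2] >= 0 & idx[, 2] <= src_shape[2] - 1 &
              idx[, 3] >= 0 & idx[, 3] <= src_shape[3] - 1
    inside[is.na(inside)] <- FALSE
    lin <- 1 + idx[, 1] + src_shape[1] * (idx[, 2] + src_shape[2] * idx[, 3])
    values[inside, ] <- src_vals[lin[inside], , drop = FALSE]
  } else {
    f0 <- floor(vox)
    t <- vox - f0
    # points exactly on the upper face use the last cell with weight 1
    for (ax in 1:3) {
      at_top <- !is.na(vox[, ax]) & vox[, ax] == src_shape[ax] - 1 & src_shape[ax] >= 2
      f0[at_top, ax] <- src_shape[ax] - 2
      t[at_top, ax] <- 1
    }
    inside <- f0[, 1] >= 0 & f0[, 1] <= src_shape[1] - 2 &
              f0[, 2] >= 0 & f0[, 2] <= src_shape[2] - 2 &
              f0[, 3] >= 0 & f0[, 3] <= src_shape[3] - 2
    inside[is.na(inside)] <- FALSE
    ii <- which(inside)
    if (length(ii)) {
      acc <- matrix(0, length(ii), ncomp)
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx == 1) t[ii, 1] else 1 - t[ii, 1]) *
             (if (dy == 1) t[ii, 2] else 1 - t[ii, 2]) *
             (if (dz == 1) t[ii, 3] else 1 - t[ii, 3])
        lin <- 1 + (f0[ii, 1] + dx) +
               src_shape[1] * ((f0[ii, 2] + dy) + src_shape[2] * (f0[ii, 3] + dz))
        acc <- acc + w * src_vals[lin, , drop = FALSE]
      }
      values[ii, ] <- acc
    }
  }
  inside[!is.finite(rowSums(values))] <- FALSE
  list(values = values, inside = inside)
}
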