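#' Per-voxel deformation gradient from a displacement field
#'
#' Computes `F = I + du/dX` with derivatives taken in physical units: finite
#' differences of the mm-valued displacement divided by the voxel spacing in
#' mm. With `scheme = "central"` the stencil needs both neighbours along each
#' axis, so the output mask is the input mask eroded by one voxel;
#' `scheme = "forward"` uses the voxel and its +1 neighbour only. Central
#' differences are second-order accurate and exact for affine displacement
#' fields.
#'
#' The grid must be axis-aligned RAS (diagonal positive linear part of the
#' affine): x = left-right, y = posterior-anterior, z = inferior-superior.
#'
#' @param field a [displacement_field()].
#' @param scheme finite-difference stencil, `"central"` (default) or
#'   `"forward"`.
#' @return object of class `deformation_gradient_field` with fields `grid`,
#'   `F` (array `c(shape, 3, 3)`, `F[..., i, j]` = dx_i/dX_j) and `mask`.
#' @export
deformation_gradient <- function(field, scheme = c("central", "forward")) {
  stopifnot(inherits(field, "displacement_field"))
  scheme <- match.arg(scheme)
  grid <- field$grid
  if (any(grid$spacing <= 0)) stop("grid spacing must be > 0")
  if (!grid_is_axis_aligned(grid)) {
    stop("deformation_gradient requires an axis-aligned RAS affine (diagonal positive linear part)")
  }
  sh <- grid$shape
  mask_in <- field$mask
  # stencil validity
  out_mask <- mask_in
  for (ax in 1:3) {
    if (scheme == "central") {
      out_mask <- out_mask & shift_logical(mask_in, ax, +1L) & shift_logical(mask_in, ax, -1L)
    } else {
      out_mask <- out_mask & shift_logical(mask_in, ax, +1L)
    }
  }
  if (!any(out_mask)) {
    stop(sprintf("mask too thin for the %s stencil: %d voxels in, 0 valid after erosion",
                 scheme, sum(mask_in)))
  }
  Farr <- array(0, c(sh, 3L, 3L))
  for (i in 1:3) {
    ui <- array(field$u[, , , i], sh)
    for (j in 1:3) {
      h <- grid$spacing[j]
      if (scheme == "central") {
        d <- (shift_numeric(ui, j, +1L) - shift_numeric(ui, j, -1L)) / (2 * h)
      } else {
        d <- (shift_numeric(ui, j, +1L) - ui) / h
      }
      Farr[, , , i, j] <- d + (i == j)
    }
  }
  # outside the valid mask F is undefined; set identity to keep values finite
  outside <- !out_mask
  if (any(outside)) {
    for (i in 1:3) for (j in 1:3) {
      Fij <- Farr[, , , i, j]
      Fij[outside] <- as.numeric(i == j)
      Farr[, , , i, j] <- Fij
    }
  }
  structure(list(grid = grid, F = Farr, mask = out_mask),
            class = "deformation_gradient_field")
}

#' Jacobian determinant map
#'
#' `JD = det(F)` per voxel: the local volume change ratio between the
#' undeformed and deformed configurations (> 1 expansion, < 1 contraction).
#' Orientation-reversing voxels (`JD <= 0`, "folding") are retained in the
#' values but counted; the count is attached as attribute `n_nonpositive` and
#' such voxels are excluded from the map's mask so they do not enter
#' statistics.
#'
#' @param gf a `deformation_gradient_field` from [deformation_gradient()].
#' @return a [scalar_map()] named "jd", with attribute `n_nonpositive`.
#' @export
jacobian_determinant <- function(gf) {
  stopifnot(inherits(gf, "deformation_gradient_field"))
  n <- prod(gf$grid$shape)
  Fm <- matrix(gf$F, n, 9)  # columns in (i,j) column-major order: F11,F21,F31,F12,...
  jd <- Fm[, 1] * (Fm[, 5] * Fm[, 9] - Fm[, 8] * Fm[, 6]) -
        Fm[, 4] * (Fm[, 2] * Fm[, 9] - Fm[, 8] * Fm[, 3]) +
        Fm[, 7] * (Fm[, 2] * Fm[, 6] - Fm[, 5] * Fm[, 3])
  jd <- array(jd, gf$grid$shape)
  folded <- gf$mask & (jd <= 0 | !is.finite(jd))
  out <- scalar_map(jd, gf$grid, gf$mask & !folded, name = "jd")
  attr(out, "n_nonpositive") <- sum(folded)
  if (any(folded)) {
    warning(sprintf("%d voxels with non-positive Jacobian determinant (folding); excluded from mask",
                    sum(folded)))
  }
  out
}

#' Lagrange (Green-Lagrange) strain tensor map
#'
#' `E = (F'F - I) / 2`, symmetric by construction. Diagonal components are
#' the directional normal strains (E_xx left-right, E_yy posterior-anterior,
#' E_zz inferior-superior); off-diagonal components are the shear strains.
#' E is invariant under rigid rotations of the deformed configuration.
#'
#' @param gf a `deformation_gradient_field`.
#' @return a [tensor_map()] named "E" (component order xx, yy, zz, xy, yz, zx).
#' @export
lagrange_strain <- function(gf) {
  stopifnot(inherits(gf, "deformation_gradient_field"))
  n <- prod(gf$grid$shape)
  Fm <- matrix(gf$F, n, 9)
  # C = F'F; C[a,b] = sum_k F[k,a] F[k,b]; columns of Fm: (k,a) col-major
  col <- function(k, a) Fm[, (a - 1L) * 3L + k]
  C <- function(a, b) col(1, a) * col(1, b) + col(2, a) * col(2, b) + col(3, a) * col(3, b)
  E6 <- cbind((C(1, 1) - 1) / 2, (C(2, 2) - 1) / 2, (C(3, 3) - 1) / 2,
              C(1, 2) / 2, C(2, 3) / 2, C(3, 1) / 2)
  tensor_map(array(E6, c(gf$grid$shape, 6L)), gf$grid, gf$mask, name = "E")
}

#' Principal stretches from a Lagrange strain map
#'
#' The eigenvalues e_i of E give the principal stretches
#' `lambda_i = sqrt(1 + 2 e_i)`: the ratio of deformed to undeformed length
#' along the i-th principal direction (unit extension `lambda_i - 1`).
#' Voxels where any e_i <= -1/2 (no real stretch) are flagged invalid and
#' removed from the mask; their count is attribute `n_invalid`.
#'
#' @param Emap a [tensor_map()] of Lagrange strain.
#' @return object of class `stretch_maps`: list of three [scalar_map()]s
#'   `lambda1 >= lambda2 >= lambda3`, shared `mask`, attribute `n_invalid`.
#' @export
principal_stretches <- function(Emap) {
  stopifnot(inherits(Emap, "tensor_map"))
  grid <- Emap$grid
  idx <- which(Emap$mask)
  v <- tensor_as_matrix(Emap, flat = TRUE)[idx, , drop = FALSE]
  e <- eig3_sym(v)                      # descending eigenvalues of E
  valid <- e[, 3] > -0.5
  lam <- sqrt(pmax(1 + 2 * e, 0))
  shp <- grid$shape
  mk_map <- function(k, nm) {
    a <- array(1, shp)                  # identity stretch outside mask
    a[idx] <- lam[, k]
    a[idx[!valid]] <- NA_real_
    scalar_map(a, grid, NULL, name = nm)
  }
  mask <- array(FALSE, shp)
  mask[idx[valid]] <- TRUE
  out <- list(lambda1 = mk_map(1, "lambda1"),
              lambda2 = mk_map(2, "lambda2"),
              lambda3 = mk_map(3, "lambda3"),
              mask = mask, grid = grid)
  out$lambda1$mask <- mask; out$lambda2$mask <- mask; out$lambda3$mask <- mask
  attr(out, "n_invalid") <- sum(!valid)
  class(out) <- "stretch_maps"
  out
}

#' Anisotropy of directional growth (ADG)
#'
#' Fractional-anisotropy-style normalised dispersion of the three principal
#' stretches:
#' `ADG = sqrt(3/2) * sqrt(sum (lambda_i - mean)^2) / sqrt(sum lambda_i^2)`.
#' ADG = 0 for isotropic growth (all stretches equal) and approaches 1 as the
#' growth becomes one-dimensional. It is invariant to permutation and to
#' positive rescaling of the stretches. `on = "strain"` applies the same
#' formula to the strain eigenvalues `e_i = (lambda_i^2 - 1)/2` instead; the
#' stretch form is the default.
#'
#' @param stretches a `stretch_maps` object from [principal_stretches()], or a
#'   3-column matrix of stretches.
#' @param on quantity the anisotropy formula is applied to: `"stretch"`
#'   (default) or `"strain"` eigenvalues.
#' @return a [scalar_map()] named "adg" (or a numeric vector for matrix input).
#' @export
adg <- function(stretches, on = c("stretch", "strain")) {
  on <- match.arg(on)
  if (is.matrix(stretches)) return(adg_values(stretches, on))
  stopifnot(inherits(stretches, "stretch_maps"))
  grid <- stretches$grid
  idx <- which(stretches$mask)
  lam <- cbind(stretches$lambda1$values[idx],
               stretches$lambda2$values[idx],
               stretches$lambda3$values[idx])
  a <- array(0, grid$shape)
  a[idx] <- adg_values(lam, on)
  scalar_map(a, grid, stretches$mask, name = "adg")
}

adg_values <- function(lam, on = "stretch") {
  if (on == "strain") lam <- (lam^2 - 1) / 2
  m <- rowMeans(lam)
  num <- sqrt((lam[, 1] - m)^2 + (lam[, 2] - m)^2 + (lam[, 3] - m)^2)
  den <- sqrt(lam[, 1]^2 + lam[, 2]^2 + lam[, 3]^2)
  out <- sqrt(1.5) * num / den
  out[den == 0] <- 0
  out
}

#' Shear deformation angles
#'
#' For each axis pair (i, j) the shear strain reduces the angle between the
#' originally perpendicular i- and j-axis line elements by
#' `theta_ij = asin(2 E_ij / (lambda_i lambda_j))`, with the axis-wise
#' stretches `lambda_i = sqrt(1 + 2 E_ii)`. The sign of theta follows the
#' sign of E_ij. Voxels with non-physical strain (|argument| > 1, or a
#' non-positive axis stretch) are flagged invalid, removed from the mask and
#' counted in attribute `n_invalid`.
#'
#' @param Emap a [tensor_map()] of Lagrange strain.
#' @return object of class `angle_maps`: list of [scalar_map()]s `theta_xy`,
#'   `theta_yz`, `theta_zx` (radians), shared `mask`, attribute `n_invalid`.
#' @export
deformation_angles <- function(Emap) {
  stopifnot(inherits(Emap, "tensor_map"))
  grid <- Emap$grid
  idx <- which(Emap$mask)
  v <- tensor_as_matrix(Emap, flat = TRUE)[idx, , drop = FALSE]
  lam2 <- 1 + 2 * v[, 1:3, drop = FALSE]      # lambda_x^2, lambda_y^2, lambda_z^2
  okdiag <- lam2[, 1] > 0 & lam2[, 2] > 0 & lam2[, 3] > 0
  lam <- sqrt(pmax(lam2, 0))
  pair <- list(xy = c(1L, 2L, 4L), yz = c(2L, 3L, 5L), zx = c(3L, 1L, 6L))
  sins <- sapply(pair, function(p) 2 * v[, p[3]] / (lam[, p[1]] * lam[, p[2]]))
  sins <- matrix(sins, ncol = 3)
  valid <- okdiag & apply(abs(sins) <= 1, 1, all)
  mask <- array(FALSE, grid$shape)
  mask[idx[valid]] <- TRUE
  mk <- function(k, nm) {
    a <- array(0, grid$shape)
    a[idx] <- ifelse(valid, asin(pmin(pmax(sins[, k], -1), 1)), NA_real_)
    scalar_map(a, grid, mask, name = nm)
  }
  out <- list(theta_xy = mk(1, "theta_xy"),
              theta_yz = mk(2, "theta_yz"),
              theta_zx = mk(3, "theta_zx"),
              mask = mask, grid = grid)
  attr(out, "n_invalid") <- sum(!valid)
  class(out) <- "angle_maps"
  out
}

#' Full finite-strain analysis of a displacement field
#'
#' Chains [deformation_gradient()], [jacobian_determinant()],
#' [lagrange_strain()], [principal_stretches()], [adg()] and
#' [deformation_angles()], propagating a single validity mask (stencil
#' erosion, folding and non-physical-strain voxels all removed) and a QC
#' summary of excluded voxel counts.
#'
#' @param field a [displacement_field()].
#' @param scheme finite-difference scheme, see [deformation_gradient()].
#' @param adg_on quantity for the anisotropy index, see [adg()].
#' @return object of class `strain_field` with elements `grid`, `mask`,
#'   `gradient`, `jd`, `E`, `stretches`, `adg`, `angles`, `qc`.
#' @export
compute_strain_field <- function(field, scheme = c("central", "forward"),
                                 adg_on = c("stretch", "strain")) {
  scheme <- match.arg(scheme)
  adg_on <- match.arg(adg_on)
  gf <- deformation_gradient(field, scheme)
  jd <- suppressWarnings(jacobian_determinant(gf))
  E <- lagrange_strain(gf)
  st <- principal_stretches(E)
  a <- adg(st, on = adg_on)
  ang <- deformation_angles(E)
  mask <- jd$mask & st$mask & ang$mask
  jd$mask <- mask
  E$mask <- mask
  st$mask <- mask; st$lambda1$mask <- mask; st$lambda2$mask <- mask; st$lambda3$mask <- mask
  a$mask <- mask
  ang$mask <- mask; ang$theta_xy$mask <- mask; ang$theta_yz$mask <- mask; ang$theta_zx$mask <- mask
  structure(list(grid = field$grid, mask = mask, gradient = gf,
                 jd = jd, E = E, stretches = st, adg = a, angles = ang,
                 qc = list(n_folding = attr(jd, "n_nonpositive"),
                           n_invalid_stretch = attr(st, "n_invalid"),
                           n_invalid_angle = attr(ang, "n_invalid"),
                           n_valid = sum(mask),
                           scheme = scheme, adg_on = adg_on,
                           adg_normalisation = "sqrt(3/2)")),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("strain_field: %s grid, %d valid voxels (%d folding, %d invalid stretch, %d invalid angle)\n",
              paste(x$grid$shape, collapse = "x"), x$qc$n_valid,
              x$qc$n_folding, x$qc$n_invalid_stretch, x$qc$n_invalid_angle))
  invisible(x)
}

# ---- internal: shifts and symmetric 3x3 eigenvalues -------------------------

# shift a 3-D array by `by` voxels along `axis`, padding with `fill`;
# result[v] = a[v + by] (neighbour lookup)
shift_numeric <- function(a, axis, by, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { dst[[axis]] <- 1:(n - by); src[[axis]] <- (1 + by):n }
  else if (by < 0) { dst[[axis]] <- (1 - by):n; src[[axis]] <- 1:(n + by) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

shift_logical <- function(a, axis, by) {
  out <- shift_numeric(array(as.numeric(a), dim(a)), axis, by, fill = 0)
  array(out != 0, dim(a))
}

# eigenvalues (descending) of symmetric 3x3 tensors given as n x 6 rows
# (xx, yy, zz, xy, yz, zx); LAPACK per voxel for machine-precision values
eig3_sym <- function(v) {
  n <- nrow(v)
  out <- matrix(NA_real_, n, 3)
  if (n == 0L) return(out)
  A <- matrix(0, 3, 3)
  for (r in seq_len(n)) {
    A[1, 1] <- v[r, 1]; A[2, 2] <- v[r, 2]; A[3, 3] <- v[r, 3]
    A[1, 2] <- A[2, 1] <- v[r, 4]
    A[2, 3] <- A[3, 2] <- v[r, 5]
    A[3, 1] <- A[1, 3] <- v[r, 6]
    out[r, ] <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  }
  out
}
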