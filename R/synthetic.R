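#' Analytic deformations with closed-form strain oracles
#'
#' Constructs a deformation whose displacement `u(X)` and deformation
#' gradient `F(X)` are evaluable in closed form at arbitrary physical
#' coordinates, giving exact reference values for the Jacobian determinant
#' and Lagrange strain against which the finite-difference pipeline is
#' validated. Kinds:
#' \describe{
#'   \item{affine}{`u = A X`, `F = I + A` (constant).}
#'   \item{rigid_rotation}{rotation by `angle` (radians) about `axis` through
#'     `center`: `F = R`, so JD = 1 and E = 0.}
#'   \item{simple_shear}{`u_i = gamma * X_j` for axis pair `(i, j)`
#'     (default x sheared by y).}
#'   \item{uniform_scale}{isotropic scaling by `s` about `center`.}
#'   \item{gaussian_expansion}{radial expansion `u = alpha g(X) (X - c)` with
#'     `g = exp(-|X - c|^2 / (2 sigma^2))`;
#'     `dU_i/dX_j = alpha g (delta_ij - d_i d_j / sigma^2)`. `alpha` must be
#'     small enough that JD > 0 everywhere (checked at construction).}
#' }
#'
#' @param kind deformation family, see above.
#' @param A 3x3 matrix (affine kind).
#' @param angle,axis rotation angle (radians) and axis (length-3) for
#'   `rigid_rotation`.
#' @param gamma shear magnitude; `shear_axes` gives the (i, j) pair.
#' @param s scale factor for `uniform_scale`.
#' @param center center of rotation/scaling/expansion (mm).
#' @param alpha,sigma amplitude (dimensionless) and width (mm) of the
#'   Gaussian expansion.
#' @return object of class `analytic_deformation` with functions `u(X)` and
#'   `F(X)` taking an n x 3 matrix of mm coordinates.
#' @export
analytic_deformation <- function(kind = c("affine", "rigid_rotation", "simple_shear",
                                          "uniform_scale", "gaussian_expansion"),
                                 A = NULL, angle = 0, axis = c(0, 0, 1),
                                 gamma = 0, shear_axes = c(1, 2), s = 1,
                                 center = c(0, 0, 0), alpha = 0.3, sigma = 10) {
  kind <- match.arg(kind)
  center <- as.numeric(center)
  obj <- switch(kind,
    affine = {
      stopifnot(is.matrix(A), all(dim(A) == c(3, 3)))
      Fc <- diag(3) + A
      list(u = function(X) X %*% t(A),
           F = function(X) constant_F(Fc, nrow(X)))
    },
    rigid_rotation = {
      R <- rotation_matrix(angle, axis)
      list(u = function(X) sweep(sweep(X, 2, center) %*% t(R - diag(3)), 2, c(0, 0, 0), "+"),
           F = function(X) constant_F(R, nrow(X)))
    },
    simple_shear = {
      i <- shear_axes[1]; j <- shear_axes[2]
      A <- matrix(0, 3, 3); A[i, j] <- gamma
      Fc <- diag(3) + A
      list(u = function(X) X %*% t(A),
           F = function(X) constant_F(Fc, nrow(X)))
    },
    uniform_scale = {
      stopifnot(s > 0)
      list(u = function(X) (s - 1) * sweep(X, 2, center),
           F = function(X) constant_F(diag(s, 3), nrow(X)))
    },
    gaussian_expansion = {
      # radial stretch 1 + alpha g (1 - r^2/sigma^2) has its minimum at
      # r^2 = 3 sigma^2; require it positive so JD > 0 everywhere
      rmin2 <- 3 * sigma^2
      min_radial <- 1 + alpha * exp(-rmin2 / (2 * sigma^2)) * (1 - rmin2 / sigma^2)
      if (min_radial <= 0 || 1 + alpha <= 0) {
        stop(sprintf("gaussian_expansion folds (alpha = %g too large for sigma = %g)", alpha, sigma))
      }
      list(
        u = function(X) {
          d <- sweep(X, 2, center)
          g <- exp(-rowSums(d^2) / (2 * sigma^2))
          alpha * g * d
        },
        F = function(X) {
          d <- sweep(X, 2, center)
          g <- exp(-rowSums(d^2) / (2 * sigma^2))
          n <- nrow(X)
          Farr <- array(0, c(n, 3, 3))
          for (i in 1:3) for (j in 1:3) {
            Farr[, i, j] <- (i == j) + alpha * g * ((i == j) - d[, i] * d[, j] / sigma^2)
          }
          Farr
        })
    })
  structure(c(obj, list(kind = kind,
                        params = list(A = A, angle = angle, axis = axis,
                                      gamma = gamma, shear_axes = shear_axes,
                                      s = s, center = center, alpha = alpha,
                                      sigma = sigma))),
            class = "analytic_deformation")
}

constant_F <- function(Fc, n) {
  Farr <- array(0, c(n, 3, 3))
  for (i in 1:3) for (j in 1:3) Farr[, i, j] <- Fc[i, j]
  Farr
}

rotation_matrix <- function(angle, axis) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Oracle strain quantities of an analytic deformation
#'
#' Evaluates the closed-form `F` at the given points and derives the exact
#' JD = det(F), Lagrange strain `E = (F'F - I)/2` and principal stretches.
#'
#' @param def an [analytic_deformation()].
#' @param X n x 3 matrix of physical coordinates (mm).
#' @return list with `F` (n x 3 x 3), `jd` (n), `E` (n x 6, order
#'   [TENSOR_COMPONENTS]).
#' @export
oracle_strain <- function(def, X) {
  Farr <- def$F(X)
  n <- nrow(X)
  Fm <- matrix(Farr, n, 9)
  jd <- Fm[, 1] * (Fm[, 5] * Fm[, 9] - Fm[, 8] * Fm[, 6]) -
        Fm[, 4] * (Fm[, 2] * Fm[, 9] - Fm[, 8] * Fm[, 3]) +
        Fm[, 7] * (Fm[, 2] * Fm[, 6] - Fm[, 5] * Fm[, 3])
  col <- function(k, a) Fm[, (a - 1L) * 3L + k]
  C <- function(a, b) col(1, a) * col(1, b) + col(2, a) * col(2, b) + col(3, a) * col(3, b)
  E6 <- cbind((C(1, 1) - 1) / 2, (C(2, 2) - 1) / 2, (C(3, 3) - 1) / 2,
              C(1, 2) / 2, C(2, 3) / 2, C(3, 1) / 2)
  colnames(E6) <- TENSOR_COMPONENTS
  list(F = Farr, jd = jd, E = E6)
}

#' Sample an analytic deformation onto a grid
#'
#' Evaluates `u` at every voxel centre and packages the result as a
#' [displacement_field()], together with oracle JD and Lagrange-strain maps
#' from the closed-form `F` for validation of the finite-difference pipeline.
#'
#' @param def an [analytic_deformation()].
#' @param grid a [volume_grid()].
#' @param mask optional logical array.
#' @return list with `field` (displacement_field), `jd` (scalar_map oracle),
#'   `E` (tensor_map oracle), `F` (array `c(shape, 3, 3)`).
#' @export
sample_field <- function(def, grid, mask = NULL) {
  stopifnot(inherits(def, "analytic_deformation"))
  X <- grid_coordinates(grid)
  uu <- def$u(X)
  orc <- oracle_strain(def, X)
  if (any(orc$jd <= 0)) {
    stop(sprintf("deformation folds on this grid: %d voxels with oracle JD <= 0",
                 sum(orc$jd <= 0)))
  }
  field <- displacement_field(array(uu, c(grid$shape, 3L)), grid, mask)
  list(field = field,
       jd = scalar_map(array(orc$jd, grid$shape), grid, field$mask, name = "jd_oracle"),
       E = tensor_map(array(orc$E, c(grid$shape, 6L)), grid, field$mask, name = "E_oracle"),
       F = array(orc$F, c(grid$shape, 3L, 3L)))
}

#' Phantom brain mask and atlas
#'
#' Builds an ellipsoidal "brain" mask (semi-axes 0.42 of the grid extent) and
#' deterministically partitions it into `n_rois` contiguous, non-empty
#' regions by slabs along the x axis with near-equal voxel counts, standing
#' in for an anatomical parcellation at desk scale.
#'
#' @param grid a [volume_grid()].
#' @param n_rois number of regions (>= 2).
#' @return a [label_atlas()]; the mask is `labels > 0`.
#' @export
make_phantom_atlas <- function(grid, n_rois) {
  stopifnot(n_rois >= 2)
  sh <- grid$shape
  ii <- (slice_index(sh, 1) - (sh[1] + 1) / 2) / (0.42 * sh[1])
  jj <- (slice_index(sh, 2) - (sh[2] + 1) / 2) / (0.42 * sh[2])
  kk <- (slice_index(sh, 3) - (sh[3] + 1) / 2) / (0.42 * sh[3])
  mask <- (ii^2 + jj^2 + kk^2) <= 1
  if (sum(mask) < n_rois) stop("grid too small for the requested number of ROIs")
  xs <- slice_index(sh, 1)[mask]
  # slab boundaries at x-quantiles -> contiguous near-equal partitions
  ranks <- (rank(xs, ties.method = "first") - 1) / length(xs)
  lab_in <- pmin(floor(ranks * n_rois) + 1L, n_rois)
  labels <- array(0L, sh)
  labels[mask] <- lab_in
  if (length(unique(lab_in)) != n_rois) stop("grid too small for the requested number of ROIs")
  nms <- stats::setNames(sprintf("ROI_%03d", seq_len(n_rois)), as.character(seq_len(n_rois)))
  label_atlas(labels, grid, nms)
}

slice_index <- function(sh, axis) {
  a <- array(0L, sh)
  if (axis == 1) a[] <- rep.int(seq_len(sh[1]), sh[2] * sh[3])
  if (axis == 2) a[] <- rep.int(rep(seq_len(sh[2]), each = sh[1]), sh[3])
  if (axis == 3) a[] <- rep(seq_len(sh[3]), each = sh[1] * sh[2])
  a
}

#' Specification of a simulated longitudinal cohort
#'
#' Defaults emulate the study design the statistics target: 33 infants
#' scanned at 5 time points across the first year (mean scan ages 26, 102,
#' 189, 279 and 372 postnatal days), giving four growth intervals with
#' midpoint ages (64, 145.5, 234, 325.5) days and inter-scan intervals of
#' (76, 87, 90, 93) days. The parameter maps follow
#' `y_ij(v) = beta0 + beta1 * age_ij * blob(v) + b_i + e_ij(v)` with subject
#' random intercept `b_i ~ N(0, sigma_b^2)` and i.i.d. voxel noise
#' `e ~ N(0, sigma_e^2)`.
#'
#' @param n_subjects number of subjects.
#' @param midpoint_ages midpoint age (days) of each interval.
#' @param days_between_scans interval lengths (days), same length.
#' @param beta0 baseline parameter value.
#' @param beta1 age effect per day (applied inside the blob; 0 outside).
#' @param sigma_b SD of the subject random intercept.
#' @param sigma_e residual SD per voxel-observation.
#' @param seed RNG seed; identical spec + seed gives an identical cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 33,
                        midpoint_ages = c(64, 145.5, 234, 325.5),
                        days_between_scans = c(76, 87, 90, 93),
                        beta0 = 0.2, beta1 = -0.002,
                        sigma_b = 0.05, sigma_e = 0.02, seed = 1) {
  stopifnot(length(midpoint_ages) == length(days_between_scans),
            n_subjects >= 2, all(days_between_scans > 0), all(midpoint_ages > 0))
  structure(list(n_subjects = n_subjects, midpoint_ages = midpoint_ages,
                 days_between_scans = days_between_scans,
                 beta0 = beta0, beta1 = beta1,
                 sigma_b = sigma_b, sigma_e = sigma_e, seed = seed),
            class = "cohort_spec")
}

#' Simulate a longitudinal cohort of parameter maps
#'
#' Draws per-(subject, interval) scalar maps under the linear mixed model of
#' [cohort_spec()]. The age effect acts only inside `blob` (a logical array;
#' `NULL` applies it everywhere in the mask), giving known ground truth for
#' sensitivity/specificity checks; `beta1 = 0` yields a global null. The
#' generator is a pure function of (spec, grid, blob): the same seed
#' reproduces the cohort exactly.
#'
#' @param spec a [cohort_spec()].
#' @param grid a [volume_grid()].
#' @param mask logical array; default all voxels.
#' @param blob logical array marking voxels carrying the age effect, or
#'   `NULL` for a spatially uniform effect.
#' @return list with `maps` (list of [scalar_map()], one per cohort row) and
#'   `cohort` (a [cohort_table()] whose rows align with `maps`).
#' @export
simulate_cohort <- function(spec, grid, mask = NULL, blob = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(grid, "volume_grid"))
  mask <- check_mask(mask, grid)
  if (is.null(blob)) blob <- mask
  stopifnot(identical(dim(blob), dim(mask)))
  nint <- length(spec$midpoint_ages)
  nv <- prod(grid$shape)
  eff <- as.numeric(blob)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  b <- stats::rnorm(spec$n_subjects, 0, spec$sigma_b)
  maps <- vector("list", spec$n_subjects * nint)
  rows <- vector("list", spec$n_subjects * nint)
  r <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (k in seq_len(nint)) {
      r <- r + 1L
      age <- spec$midpoint_ages[k]
      vals <- spec$beta0 + spec$beta1 * age * eff + b[s] +
        stats::rnorm(nv, 0, spec$sigma_e)
      maps[[r]] <- scalar_map(array(vals, grid$shape), grid, mask,
                              name = sprintf("sub%03d_int%d", s, k))
      rows[[r]] <- data.frame(subject_id = sprintf("sub%03d", s),
                              interval_id = k,
                              days_between_scans = spec$days_between_scans[k],
                              midpoint_age_days = age)
    }
  }
  list(maps = maps, cohort = cohort_table(do.call(rbind, rows)))
}
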