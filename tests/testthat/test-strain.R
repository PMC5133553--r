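test_that("central differences are exact for affine displacement fields", {
  r <- strain_of(analytic_deformation("affine", A = diag(0.1, 3)))
  idx <- which(r$sf$mask)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(max(abs(r$sf$gradient$F[, , , i, j][idx] - (if (i == j) 1.1 else 0))), 0)
  }

  zero <- displacement_field(array(0, c(8, 8, 8, 3)), centred_grid(8))
  sfz <- compute_strain_field(zero)
  iz <- which(sfz$mask)
  expect_true(all(sfz$jd$values[iz] == 1))
  expect_true(all(sfz$E$values[mask_k(sfz$mask, 6)] == 0))
  expect_true(all(sfz$stretches$lambda1$values[iz] == 1))
  expect_true(all(sfz$adg$values[iz] == 0))
  expect_true(all(sfz$angles$theta_xy$values[iz] == 0))
})

test_that("simple shear gives the hand-computed F, E, JD and shear angle", {
  r <- strain_of(analytic_deformation("simple_shear", gamma = 0.2))
  idx <- which(r$sf$mask)
  expect_equal(max(abs(r$sf$gradient$F[, , , 1, 2][idx] - 0.2)), 0)
  expect_equal(max(abs(r$sf$gradient$F[, , , 1, 1][idx] - 1)), 0)
  expect_equal(max(abs(r$sf$gradient$F[, , , 2, 1][idx])), 0)
  # E = [[0, 0.1, 0], [0.1, 0.02, 0], [0, 0, 0]]
  E <- r$sf$E$values
  expect_equal(max(abs(E[, , , 4][idx] - 0.1)), 0)            # E_xy
  expect_equal(max(abs(E[, , , 2][idx] - 0.02)), 0)           # E_yy
  expect_equal(max(abs(E[, , , 1][idx])), 0)                  # E_xx
  expect_equal(max(abs(r$sf$jd$values[idx] - 1)), 0, tolerance = 1e-14)
  # theta_xy = arcsin(gamma / sqrt(1 + gamma^2)) = arctan(gamma)
  expect_equal(r$sf$angles$theta_xy$values[idx], rep(atan(0.2), length(idx)),
               tolerance = 1e-12)
  expect_equal(max(abs(r$sf$angles$theta_yz$values[idx])), 0)
})

test_that("JD matches direct determinants, including the diag(1, 2, 0.5) volume-preserving case", {
  # eigenvalues {1, 2, 0.5} with zero off-diagonals: expansion and shrink cancel
  r <- strain_of(analytic_deformation("affine", A = diag(c(0, 1, -0.5))))
  idx <- which(r$sf$mask)
  expect_equal(unique(r$sf$jd$values[idx]), 1)

  r2 <- strain_of(analytic_deformation("uniform_scale", s = 1.2))
  idx2 <- which(r2$sf$mask)
  expect_equal(max(abs(r2$sf$jd$values[idx2] - 1.728)), 0, tolerance = 1e-12)
  expect_equal(max(abs(r2$sf$E$values[, , , 1][idx2] - 0.22)), 0, tolerance = 1e-12)
  expect_equal(max(abs(r2$sf$stretches$lambda1$values[idx2] - 1.2)), 0, tolerance = 1e-12)
})

test_that("orientation-reversing voxels are counted and excluded", {
  g <- centred_grid(8)
  X <- strainmorph:::grid_coordinates(g)
  u <- cbind(-1.5 * X[, 1], 0, 0)                 # F = diag(-0.5, 1, 1): det < 0
  f <- displacement_field(array(u, c(g$shape, 3)), g)
  gf <- deformation_gradient(f)
  expect_warning(jd <- jacobian_determinant(gf), "non-positive")
  expect_gt(attr(jd, "n_nonpositive"), 0)
  expect_false(any(jd$mask & jd$values <= 0))
})

test_that("principal stretches invert the strain eigenvalues", {
  g <- volume_grid(c(2, 2, 2))
  # E = diag(1.5, 0, -0.375) -> lambda = (2, 1, 0.5)
  ev <- array(rep(c(1.5, 0, -0.375, 0, 0, 0), each = 8), c(2, 2, 2, 6))
  st <- principal_stretches(tensor_map(ev, g))
  expect_equal(st$lambda1$values[1, 1, 1], 2)
  expect_equal(st$lambda2$values[1, 1, 1], 1)
  expect_equal(st$lambda3$values[1, 1, 1], 0.5)
  expect_identical(attr(st, "n_invalid"), 0L)

  # e3 <= -1/2 has no real stretch: voxel flagged invalid
  bad <- array(rep(c(0, 0, -0.6, 0, 0, 0), each = 8), c(2, 2, 2, 6))
  st2 <- principal_stretches(tensor_map(bad, g))
  expect_identical(attr(st2, "n_invalid"), 8L)
  expect_false(any(st2$mask))
})

test_that("ADG is zero for isotropy, approaches 1 for 1-D growth, and is scale/permutation invariant", {
  expect_equal(adg(matrix(c(3, 3, 3), 1)), 0)
  expect_equal(adg(matrix(c(0.1, 0.1, 0.1), 1)), 0)
  # lambda = (2, 1, 1): mean 4/3, deviations (2/3, -1/3, -1/3)
  # ADG = sqrt(3/2) * sqrt(4/9 + 2/9) / sqrt(6) = sqrt(1/6)
  expect_equal(adg(matrix(c(2, 1, 1), 1)), sqrt(1.5) * sqrt(4 / 9 + 2 / 9) / sqrt(6),
               tolerance = 1e-12)
  expect_equal(adg(matrix(c(2, 1, 1), 1)), 0.40824829, tolerance = 1e-6)
  # monotone approach to 1 as growth becomes one-dimensional
  eps <- 10^seq(-1, -6)
  vals <- adg(cbind(1, eps, eps))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 1) && vals[length(vals)] > 0.999)
  # permutation and positive-scaling invariance on random stretches
  set.seed(5)
  lam <- matrix(runif(300, 0.5, 2), 100, 3)
  base <- adg(lam)
  expect_equal(adg(lam[, c(3, 1, 2)]), base, tolerance = 1e-12)
  expect_equal(adg(lam * 7.3), base, tolerance = 1e-12)
  expect_true(all(base >= 0 & base < 1))
})

test_that("rigid rotations produce no strain (objectivity of E)", {
  for (ang in c(pi / 6, pi / 2, 1.2)) {
    r <- strain_of(analytic_deformation("rigid_rotation", angle = ang, axis = c(1, 2, 2)))
    idx <- which(r$sf$mask)
    expect_lt(max(abs(r$sf$E$values[mask_k(r$sf$mask, 6)])), 1e-10)
    expect_lt(max(abs(r$sf$jd$values[idx] - 1)), 1e-10)
  }
  # composing a deformation with a rigid rotation of the deformed configuration
  # leaves E unchanged: x' = R(X + u) => u' = R(X + u) - X
  g <- centred_grid(10)
  X <- strainmorph:::grid_coordinates(g)
  gam <- 0.15
  u <- cbind(gam * X[, 2], 0, 0)
  R <- strainmorph:::rotation_matrix(0.7, c(0, 0, 1))
  u_rot <- (X + u) %*% t(R) - X
  f1 <- displacement_field(array(u, c(g$shape, 3)), g)
  f2 <- displacement_field(array(u_rot, c(g$shape, 3)), g)
  E1 <- lagrange_strain(deformation_gradient(f1))
  E2 <- lagrange_strain(deformation_gradient(f2))
  expect_equal(E2$values[mask_k(E2$mask, 6)], E1$values[mask_k(E1$mask, 6)],
               tolerance = 1e-12)
})

test_that("determinant, trace and stretch identities hold on random smooth fields", {
  set.seed(7)
  for (rep in 1:5) {
    A <- matrix(rnorm(9, sd = 0.05), 3, 3)
    def_a <- analytic_deformation("affine", A = A)
    def_g <- analytic_deformation("gaussian_expansion",
                                  alpha = runif(1, 0.05, 0.25),
                                  sigma = runif(1, 8, 14),
                                  center = rnorm(3, sd = 3))
    g <- centred_grid(10)
    X <- strainmorph:::grid_coordinates(g)
    u <- def_a$u(X) + def_g$u(X)
    sf <- compute_strain_field(displacement_field(array(u, c(g$shape, 3)), g))
    idx <- which(sf$mask)
    lam <- cbind(sf$stretches$lambda1$values[idx],
                 sf$stretches$lambda2$values[idx],
                 sf$stretches$lambda3$values[idx])
    jd <- sf$jd$values[idx]
    expect_lt(max(abs(jd - lam[, 1] * lam[, 2] * lam[, 3])), 1e-8)
    trE <- sf$E$values[, , , 1][idx] + sf$E$values[, , , 2][idx] + sf$E$values[, , , 3][idx]
    expect_lt(max(abs(trE - (rowSums(lam^2) - 3) / 2)), 1e-10)
  }
})

test_that("finite-difference error on a smooth field shrinks at second order", {
  def <- analytic_deformation("gaussian_expansion", alpha = 0.3, sigma = 10)
  err <- sapply(c(4, 2), function(h) {
    n <- 64 / h
    s <- sample_field(def, centred_grid(n, h))
    sf <- compute_strain_field(s$field)
    idx <- which(sf$mask)
    max(abs(sf$jd$values[idx] - s$jd$values[idx]))
  })
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5)
})

test_that("masks too thin for the stencil and non-physical shear strains are rejected", {
  g <- centred_grid(6)
  mask <- array(FALSE, g$shape); mask[3, 3, 3] <- TRUE   # single voxel: no neighbours
  f <- displacement_field(array(0, c(g$shape, 3)), g, mask)
  expect_error(deformation_gradient(f), "too thin")

  # |2 E_xy| > lambda_x lambda_y is not a physical strain state
  ev <- array(rep(c(0, 0, 0, 2, 0, 0), each = 8), c(2, 2, 2, 6))
  ang <- deformation_angles(tensor_map(ev, volume_grid(c(2, 2, 2))))
  expect_identical(attr(ang, "n_invalid"), 8L)
  expect_false(any(ang$mask))
})
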