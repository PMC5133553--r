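test_that("one-sample t map matches hand-computed values and handles degenerate voxels", {
  g <- volume_grid(c(2, 2, 1))
  maps <- lapply(c(1.1, 1.2, 1.3), const_map, grid = g)
  res <- one_sample_t_map(maps, null_value = 1)
  expect_equal(unique(as.vector(res$t$values)), 3.4641016, tolerance = 1e-6)
  expect_identical(res$df, 2)
  expect_equal(unique(as.vector(res$p$values)), 0.0741799, tolerance = 1e-5)

  # all subjects at the null: zero variance -> t = 0, p = 1
  null_maps <- lapply(rep(1, 4), const_map, grid = g)
  r0 <- one_sample_t_map(null_maps, null_value = 1)
  expect_true(all(r0$t$values == 0) && all(r0$p$values == 1))

  # antisymmetric sample around the null: mean = null -> t = 0
  anti <- lapply(c(0.9, 1.1, 0.8, 1.2), const_map, grid = g)
  ra <- one_sample_t_map(anti, null_value = 1)
  expect_true(all(ra$t$values == 0))

  # zero variance away from the null is flagged
  off <- lapply(rep(2, 3), const_map, grid = g)
  ro <- one_sample_t_map(off, null_value = 1)
  expect_true(all(ro$p$values == 0))
  expect_identical(attr(ro, "n_zero_variance_nonnull"), 4L)

  expect_error(one_sample_t_map(maps[1:2], 1), "at least 3")
})

test_that("BH step-up matches the hand-worked example and a brute-force threshold search", {
  r <- bh_fdr(c(0.005, 0.011, 0.02, 0.04, 0.13), q = 0.05)
  expect_identical(r$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))  # p(4)=0.04 <= 4*0.05/5

  r1 <- bh_fdr(rep(1, 6))
  expect_false(any(r1$reject))
  expect_true(all(r1$p_adjusted == 1))
  expect_equal(bh_fdr(0.031)$p_adjusted, 0.031)                  # m = 1: adjusted = raw
  expect_length(bh_fdr(numeric(0))$reject, 0)
  expect_true(all(bh_fdr(c(0.2, 0.01))$p_adjusted >= c(0.2, 0.01)))

  set.seed(19)
  for (rep in 1:50) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(bh_fdr(p, q)$reject, bh_bruteforce_reject(p, q))
  }
})

test_that("raw rejections under a simulated null stay near the nominal level and BH controls them", {
  set.seed(101)
  g <- volume_grid(c(50, 40, 5))   # 10,000 voxels
  n <- 12
  maps <- lapply(seq_len(n), function(i) scalar_map(array(rnorm(10000, 1, 0.1), g$shape), g))
  res <- one_sample_t_map(maps, null_value = 1)
  rate <- mean(res$p$values < 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / 10000)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
  expect_lte(mean(res$significant), 0.05)
})

test_that("profiled REML reduces to OLS for balanced independent data and solves the balanced toy exactly", {
  # balanced design: GLS and OLS fixed effects coincide for any variance ratio
  set.seed(23)
  ages <- c(60, 150, 230, 320)
  d <- expand.grid(subject_id = 1:10, age = ages)
  d$y <- 0.5 - 0.001 * d$age + rnorm(nrow(d), 0, 0.05)   # independent errors
  f <- fit_lme(d)
  ols <- coef(lm(y ~ age, data = d))
  expect_equal(unname(f$beta), unname(ols), tolerance = 1e-6)

  toy <- data.frame(subject_id = c("A", "A", "B", "B"),
                    age = c(10, 20, 10, 20), y = c(1, 2, 2, 3))
  ft <- fit_lme(toy)
  expect_equal(unname(ft$beta["age"]), 0.1, tolerance = 1e-10)

  expect_error(fit_lme(data.frame(subject_id = 1:4, age = 5, y = rnorm(4))), "singular|constant")
})

test_that("profiled REML agrees with lme4 on random small datasets", {
  skip_if_not_installed("lme4")
  set.seed(42)
  for (r in 1:20) {
    ns <- sample(4:10, 1); ni <- sample(3:6, 1)
    d <- do.call(rbind, lapply(seq_len(ns), function(s) {
      data.frame(subject_id = s, age = runif(ni, 0, 10), y = NA_real_)
    }))
    b <- rnorm(ns, 0, runif(1, 0.1, 1))
    d$y <- 1 + 0.3 * d$age + b[d$subject_id] + rnorm(nrow(d), 0, 0.5)
    f <- fit_lme(d)
    m <- lme4::lmer(y ~ age + (1 | subject_id), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-4)
    expect_equal(f$sigma2_e, vc$vcov[2], tolerance = 1e-4)
    expect_equal(f$sigma2_b, vc$vcov[1], tolerance = 1e-4 * max(vc$vcov[1], 1))
  }
})

test_that("the voxel-wise age model recovers a localised negative age effect", {
  g <- volume_grid(c(8, 8, 4))
  blob <- array(FALSE, g$shape); blob[3:6, 3:6, 2:3] <- TRUE
  spec <- cohort_spec(n_subjects = 33, beta1 = -0.003, sigma_e = 0.01, seed = 77)
  sim <- simulate_cohort(spec, g, blob = blob)
  res <- voxelwise_lme(sim$maps, sim$cohort, q = 0.05)
  sens <- mean(res$significant[blob])
  fpf <- mean(res$significant[!blob])
  expect_gte(sens, 0.8)
  expect_lte(fpf, 0.05)
  expect_true(all(res$slope$values[blob] < 0))   # decreasing growth rate with age

  # constant-in-age maps: slope 0, nothing significant
  flat <- lapply(seq_len(nrow(sim$cohort)), function(i) const_map(2, g))
  # add subject offsets so the design is not fully degenerate
  offs <- rnorm(33, 0, 0.1)[as.integer(factor(sim$cohort$subject_id))]
  flat <- lapply(seq_along(flat), function(i) const_map(2 + offs[i], g))
  rf <- voxelwise_lme(flat, sim$cohort)
  expect_lt(max(abs(rf$slope$values[rf$mask])), 1e-8)
  expect_false(any(rf$significant))
})

test_that("ROI classification applies whole-brain quartile thresholds to ROI means", {
  # 5 masked voxels whose type-7 quartiles are exactly 1.2 and 1.8
  g <- volume_grid(c(5, 1, 1))
  vals <- array(c(1.8, 2.0, 1.5, 1.2, 1.0), g$shape)
  labs <- array(c(1L, 1L, 2L, 3L, 3L), g$shape)
  atlas <- label_atlas(labs, g, c("1" = "A", "2" = "B", "3" = "C"))
  m <- scalar_map(vals, g)
  cls <- classify_growth(m, atlas)
  expect_equal(attr(cls, "p_lower"), 1.2)
  expect_equal(attr(cls, "p_upper"), 1.8)
  expect_equal(cls$mean, c(1.9, 1.5, 1.1))
  expect_identical(cls$classification, c("fast", "neither", "slow"))

  # uniform map: p25 = p75 = value, strict inequalities fail everywhere
  u <- const_map(1.3, g)
  cu <- classify_growth(u, atlas)
  expect_true(all(cu$classification == "neither"))

  # direct threshold: ROI of 2.0s against whole-brain p75 of 1.5
  g2 <- volume_grid(c(8, 1, 1))
  v2 <- array(c(2, 2, 1, 1.2, 1.3, 1.4, 1.5, 1.6), g2$shape)
  a2 <- label_atlas(array(c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L), g2$shape), g2,
                    c("1" = "A", "2" = "rest"))
  c2 <- classify_growth(scalar_map(v2, g2), a2)
  expect_identical(c2$classification[c2$name == "A"], "fast")

  # percentile is permutation invariant
  set.seed(9)
  perm <- sample(8)
  c3 <- classify_growth(scalar_map(array(v2[perm], g2$shape), g2,
                                   name = "jd"),
                        label_atlas(array(as.integer(a2$labels[perm]), g2$shape), g2,
                                    c("1" = "A", "2" = "rest")))
  expect_equal(attr(c3, "p_upper"), attr(c2, "p_upper"))

  # empty ROI excluded with warning
  g3 <- volume_grid(c(4, 1, 1))
  a3 <- label_atlas(array(c(1L, 1L, 0L, 0L), g3$shape), g3, c("1" = "A"))
  mask <- array(c(TRUE, TRUE, TRUE, TRUE), g3$shape)
  m3 <- scalar_map(array(1:4 / 2, g3$shape), g3, mask)
  a3b <- label_atlas(array(c(1L, 1L, 2L, 0L), g3$shape), g3, c("1" = "A", "2" = "B"))
  m3b <- scalar_map(array(1:4 / 2, g3$shape), g3,
                    array(c(TRUE, TRUE, FALSE, FALSE), g3$shape))
  expect_warning(s <- roi_summarize(m3b, a3b), "empty")
  expect_identical(s$name, "A")
})
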