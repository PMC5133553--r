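#' Voxel-wise one-sample t-test against a growth null
#'
#' Tests, at every masked voxel, whether the mean of the per-subject parameter
#' maps differs from the no-growth null (JD = 1, strain = 0): `t = (mean -
#' null) / (sd / sqrt(n))` with `n - 1` degrees of freedom and a two-sided
#' p-value. Zero-variance voxels get p = 1 when the mean equals the null
#' exactly, otherwise p = 0 and the voxel is flagged (attribute
#' `n_zero_variance_nonnull`). Benjamini-Hochberg FDR correction is applied
#' across the masked voxels.
#'
#' @param maps list of [scalar_map()]s, one per subject, on a common grid.
#' @param null_value null-hypothesis value (1 for JD, 0 for strains/angles).
#' @param q FDR level for the significance mask.
#' @return object of class `voxel_test_result`: scalar maps `mean`, `t`,
#'   `p`, `p_adjusted`, logical `significant` array, plus `df`, `n`, `q`.
#' @export
one_sample_t_map <- function(maps, null_value, q = 0.05) {
  if (length(maps) < 3L) stop("one_sample_t_map needs at least 3 subjects")
  grid <- maps[[1]]$grid
  mask <- maps[[1]]$mask
  for (m in maps[-1]) {
    stop_if_grid_mismatch(grid, m$grid, "subject maps")
    mask <- mask & m$mask
  }
  n <- length(maps)
  idx <- which(mask)
  Y <- vapply(maps, function(m) m$values[idx], numeric(length(idx)))
  mu <- rowMeans(Y)
  sdv <- sqrt(rowSums((Y - mu)^2) / (n - 1))
  tval <- rep(0, length(idx))
  p <- rep(1, length(idx))
  nz <- sdv > 0
  tval[nz] <- (mu[nz] - null_value) / (sdv[nz] / sqrt(n))
  p[nz] <- 2 * stats::pt(-abs(tval[nz]), df = n - 1)
  zero_nonnull <- !nz & mu != null_value
  p[zero_nonnull] <- 0
  tval[zero_nonnull] <- Inf * sign(mu[zero_nonnull] - null_value)
  fdr <- bh_fdr(p, q = q)
  mk <- function(x, nm, fill = NA_real_) {
    a <- array(fill, grid$shape); a[idx] <- x
    scalar_map(a, grid, mask, name = nm)
  }
  sig <- array(FALSE, grid$shape)
  sig[idx] <- fdr$reject
  out <- list(mean = mk(mu, "mean"), t = mk(tval, "t"), p = mk(p, "p"),
              p_adjusted = mk(fdr$p_adjusted, "p_adjusted"),
              significant = sig, mask = mask, grid = grid,
              df = n - 1, n = n, q = q, null_value = null_value)
  attr(out, "n_zero_variance_nonnull") <- sum(zero_nonnull)
  class(out) <- "voxel_test_result"
  out
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure: with p-values sorted ascending, reject all hypotheses
#' up to the largest k with `p(k) <= k q / m`. Adjusted p-values are
#' `min over j >= i of m p(j) / j`, capped at 1 (monotone non-decreasing in
#' rank), computed with [stats::p.adjust()]; the rejection set is exactly
#' `adjusted p <= q`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q target FDR level.
#' @return list with `p_adjusted` and logical `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0L) return(list(p_adjusted = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Random-intercept linear mixed model fitted by profiled REML
#'
#' Fits `y_ij = beta0 + beta1 * age_ij + b_i + e_ij`, with a random intercept
#' `b_i ~ N(0, sigma_b^2)` per subject and residual `e_ij ~ N(0, sigma_e^2)`,
#' the model used for age effects on longitudinal growth parameters. The REML
#' criterion is profiled down to the single variance ratio `gamma = sigma_b^2
#' / sigma_e^2`: for fixed gamma the GLS estimate of beta and the residual
#' variance are closed-form (block-diagonal covariance, one block per
#' subject), and gamma is found by 1-D minimisation of the profiled
#' criterion, with the boundary gamma = 0 checked explicitly. Wald t-tests
#' use `df = n_obs - n_subjects - rank(X) + 1`.
#'
#' @param data data.frame with columns `subject_id`, `midpoint_age` (or
#'   `midpoint_age_days` / `age`), and `y`.
#' @param tol convergence tolerance of the 1-D search on log(gamma).
#' @return object of class `lme_fit`: `beta` (intercept, age slope), `se`,
#'   `t`, `p`, `df`, `sigma2_b`, `sigma2_e`, `gamma`, `reml_loglik`,
#'   `n_subjects`, `n_obs`.
#' @export
fit_lme <- function(data, tol = 1e-10) {
  age_col <- intersect(c("midpoint_age", "midpoint_age_days", "age"), names(data))[1]
  if (is.na(age_col)) stop("data needs an age column (midpoint_age / midpoint_age_days / age)")
  if (!all(c("subject_id", "y") %in% names(data))) stop("data needs columns subject_id and y")
  y <- as.numeric(data$y)
  age <- as.numeric(data[[age_col]])
  g <- as.integer(factor(data$subject_id))
  keep <- is.finite(y) & is.finite(age) & !is.na(g)
  y <- y[keep]; age <- age[keep]; g <- g[keep]
  n <- length(y)
  ns <- length(unique(g))
  if (ns < 2L || n < 4L) stop("need >= 2 observations from each of >= 2 subjects")
  if (stats::sd(age) == 0) stop("age is constant: fixed-effect design is singular")
  X <- cbind(intercept = 1, age = age)
  fit <- lme_profile_fit(y, X, g, tol = tol)
  se <- sqrt(diag(fit$vcov_beta))
  df <- n - ns - ncol(X) + 1L
  tstat <- fit$beta / se
  p <- 2 * stats::pt(-abs(tstat), df = max(df, 1L))
  structure(list(beta = stats::setNames(fit$beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 t = stats::setNames(tstat, colnames(X)),
                 p = stats::setNames(p, colnames(X)),
                 df = df,
                 sigma2_b = fit$sigma2_b, sigma2_e = fit$sigma2_e,
                 gamma = fit$gamma, reml_loglik = fit$reml_loglik,
                 n_subjects = ns, n_obs = n),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("random-intercept LME (REML): %d obs, %d subjects\n", x$n_obs, x$n_subjects))
  print(data.frame(beta = x$beta, se = x$se, t = x$t, p = x$p))
  cat(sprintf("sigma_b = %.6g, sigma_e = %.6g, REML logLik = %.4f\n",
              sqrt(x$sigma2_b), sqrt(x$sigma2_e), x$reml_loglik))
  invisible(x)
}

# profiled REML for y = X beta + Zb + e with random intercept by group g.
# V0 = I + gamma * J within each group; closed-form GLS via group sums.
lme_profile_fit <- function(y, X, g, tol = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  gi <- match(g, unique(g))
  sizes <- tabulate(gi)
  crit <- function(gamma) lme_gls(y, X, gi, sizes, gamma)$neg2reml
  # search on log(gamma), plus explicit boundary at gamma = 0
  opt <- stats::optimize(function(th) crit(exp(th)), interval = c(-30, 15), tol = tol)
  cands <- list(c(0, crit(0)), c(exp(opt$minimum), opt$objective))
  best <- cands[[which.min(vapply(cands, `[`, numeric(1), 2))]]
  gamma <- best[1]
  sol <- lme_gls(y, X, gi, sizes, gamma)
  list(beta = sol$beta, vcov_beta = sol$vcov_beta,
       sigma2_e = sol$sigma2, sigma2_b = gamma * sol$sigma2, gamma = gamma,
       reml_loglik = -0.5 * (sol$neg2reml + (n - p) * log(2 * pi)))
}

lme_gls <- function(y, X, gi, sizes, gamma) {
  n <- length(y)
  p <- ncol(X)
  shrink <- gamma / (1 + gamma * sizes)
  # V0^-1 x = x - gamma/(1+gamma*n_i) * 1 (1' x) per group
  apply_vinv <- function(M) {
    cs <- rowsum(M, gi, reorder = TRUE)
    M - shrink[gi] * cs[gi, , drop = FALSE]
  }
  ViX <- apply_vinv(X)
  Viy <- apply_vinv(matrix(y))
  XtViX <- crossprod(X, ViX)
  XtViy <- crossprod(X, Viy)
  beta <- drop(solve(XtViX, XtViy))
  r <- y - drop(X %*% beta)
  rss <- sum(r * apply_vinv(matrix(r)))
  sigma2 <- rss / (n - p)
  logdetV0 <- sum(log1p(gamma * sizes))
  neg2reml <- (n - p) * log(sigma2) + logdetV0 +
    determinant(XtViX, logarithm = TRUE)$modulus[1] + (n - p)
  list(beta = beta, vcov_beta = sigma2 * solve(XtViX),
       sigma2 = sigma2, neg2reml = neg2reml)
}

#' Voxel-wise mixed-effects age model
#'
#' At every masked voxel, fits the random-intercept model of [fit_lme()] with
#' the interval-adjusted parameter value as response and midpoint age as the
#' fixed effect, then applies BH-FDR across voxels to the age-slope p-values.
#'
#' @param maps list of [scalar_map()]s, one per cohort row (same order as
#'   `cohort`), on a common grid.
#' @param cohort a [cohort_table()] with one row per (subject, interval).
#' @param q FDR level.
#' @return object of class `voxelwise_lme_result`: scalar maps `slope`
#'   (beta1 per day of age), `intercept`, `p`, `p_adjusted`; logical
#'   `significant`; `n_failed` voxels where the fit failed (masked out).
#' @export
voxelwise_lme <- function(maps, cohort, q = 0.05) {
  cohort <- cohort_table(as.data.frame(cohort))
  if (length(maps) != nrow(cohort)) {
    stop("need exactly one map per cohort row, in row order")
  }
  grid <- maps[[1]]$grid
  mask <- maps[[1]]$mask
  for (m in maps[-1]) {
    stop_if_grid_mismatch(grid, m$grid, "cohort maps")
    mask <- mask & m$mask
  }
  idx <- which(mask)
  Y <- vapply(maps, function(m) m$values[idx], numeric(length(idx)))
  age <- as.numeric(cohort$midpoint_age_days)
  g <- as.integer(factor(cohort$subject_id))
  X <- cbind(intercept = 1, age = age)
  groups <- split(seq_len(nrow(cohort)), g)
  sizes <- lengths(groups)
  nv <- length(idx)
  slope <- intercept <- pval <- rep(NA_real_, nv)
  failed <- logical(nv)
  ns <- length(sizes)
  df <- nrow(cohort) - ns - 1L
  for (v in seq_len(nv)) {
    yv <- Y[v, ]
    fit <- tryCatch(lme_profile_fit(yv, X, g, tol = 1e-8), error = function(e) NULL)
    if (is.null(fit)) { failed[v] <- TRUE; next }
    slope[v] <- fit$beta[2]
    intercept[v] <- fit$beta[1]
    se <- sqrt(fit$vcov_beta[2, 2])
    pval[v] <- if (se > 0) 2 * stats::pt(-abs(fit$beta[2] / se), df = max(df, 1L)) else 1
  }
  ok <- !failed & is.finite(pval)
  fdr <- bh_fdr(pval[ok], q = q)
  padj <- rep(NA_real_, nv)
  padj[ok] <- fdr$p_adjusted
  out_mask <- array(FALSE, grid$shape); out_mask[idx[ok]] <- TRUE
  mk <- function(x, nm) { a <- array(NA_real_, grid$shape); a[idx] <- x; scalar_map(a, grid, out_mask, nm) }
  sig <- array(FALSE, grid$shape)
  sig[idx[ok]] <- fdr$reject
  structure(list(slope = mk(slope, "age_slope"), intercept = mk(intercept, "intercept"),
                 p = mk(pval, "p"), p_adjusted = mk(padj, "p_adjusted"),
                 significant = sig, mask = out_mask, grid = grid,
                 df = df, q = q, n_failed = sum(failed)),
            class = "voxelwise_lme_result")
}

#' ROI summaries and fast/slow growth classification
#'
#' `roi_summarize` computes the arithmetic mean of a parameter map over the
#' masked voxels of each atlas region. `classify_growth` then classifies each
#' region against the whole-brain voxel distribution: regions whose mean
#' exceeds the 75th percentile of the parameter over *all* masked voxels are
#' "fast" growing, regions below the 25th percentile "slow", the rest
#' "neither". Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7) and are permutation-invariant.
#'
#' @param map a [scalar_map()].
#' @param atlas a [label_atlas()] on the same grid.
#' @return `roi_summarize`: data.frame with `label`, `name`, `n_voxels`,
#'   `mean`. Empty regions are dropped with a warning.
#' @export
roi_summarize <- function(map, atlas) {
  stopifnot(inherits(map, "scalar_map"), inherits(atlas, "label_atlas"))
  stop_if_grid_mismatch(map$grid, atlas$grid, "map and atlas")
  keep <- map$mask & atlas$labels > 0L
  labs <- atlas$labels[keep]
  vals <- map$values[keep]
  all_labels <- as.integer(names(atlas$names))
  agg <- tapply(vals, factor(labs, levels = all_labels), mean)
  cnt <- tapply(vals, factor(labs, levels = all_labels), length)
  empty <- is.na(agg)
  if (any(empty)) {
    warning(sprintf("excluding %d empty ROI(s): %s", sum(empty),
                    paste(atlas$names[empty], collapse = ", ")))
  }
  data.frame(label = all_labels[!empty],
             name = unname(atlas$names[!empty]),
             n_voxels = as.integer(cnt[!empty]),
             mean = as.numeric(agg[!empty]),
             row.names = NULL)
}

#' @rdname roi_summarize
#' @param probs lower/upper whole-brain percentiles defining slow and fast
#'   growth (default 25th and 75th).
#' @return `classify_growth`: data.frame as `roi_summarize` plus
#'   `classification` in fast/slow/neither; attributes `p_lower`/`p_upper`
#'   hold the whole-brain thresholds.
#' @export
classify_growth <- function(map, atlas, probs = c(0.25, 0.75)) {
  summ <- roi_summarize(map, atlas)
  vals <- map$values[map$mask]
  qs <- stats::quantile(vals, probs = probs, names = FALSE, type = 7)
  cls <- ifelse(summ$mean > qs[2], "fast", ifelse(summ$mean < qs[1], "slow", "neither"))
  summ$classification <- cls
  attr(summ, "p_lower") <- qs[1]
  attr(summ, "p_upper") <- qs[2]
  attr(summ, "percentile_definition") <- "linear interpolation (type 7)"
  summ
}
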