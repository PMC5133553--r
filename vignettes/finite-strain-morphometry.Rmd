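---
title: "Finite-strain morphometry of longitudinal deformation fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-strain morphometry of longitudinal deformation fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmorph)
```

## The model

Tensor-based morphometry summarises local brain growth by the Jacobian
determinant of a nonlinear registration, which captures volume change but
discards direction. `strainmorph` extends this with the finite-strain
apparatus of continuum mechanics. Given a displacement field $u(X)$ on a
voxel grid, with the pull-from-reference convention $x = X + u(X)$ mapping
the undeformed (earlier-time) position $X$ to the deformed position $x$, the
package computes per voxel:

* the **deformation gradient** $F = I + \partial u / \partial X$
  (dimensionless; derivatives taken in physical mm);
* the **Jacobian determinant** $JD = \det F$, the local volume change ratio
  ($>1$ expansion, $<1$ contraction);
* the **Lagrange strain** $E = \tfrac12 (F^\top F - I)$, symmetric and
  invariant under rigid rotations of the deformed configuration; its diagonal
  components are directional normal strains (x = left–right,
  y = posterior–anterior, z = inferior–superior), its off-diagonals shear
  strains;
* the **principal stretches** $\lambda_i = \sqrt{1 + 2 e_i}$, where $e_i$ are
  the eigenvalues of $E$; $\lambda_i - 1$ is the unit extension along the
  $i$-th principal direction;
* the **anisotropy of directional growth (ADG)**, the fractional-anisotropy
  formula applied to the stretches,
  $\mathrm{ADG} = \sqrt{3/2}\,\|\lambda - \bar\lambda\| / \|\lambda\|$,
  zero for isotropic growth and approaching 1 for one-dimensional growth;
* the **shear deformation angles**
  $\theta_{ij} = \arcsin\!\big(2E_{ij} / (\lambda_i \lambda_j)\big)$ with
  axis-wise $\lambda_i = \sqrt{1 + 2E_{ii}}$: the reduction of the angle
  between initially perpendicular axis-aligned line elements.

The point of the extension is that $JD$ alone is blind to direction: a voxel
with Jacobian eigenvalues $\{1, 2, 0.5\}$ and zero off-diagonals has
$JD = 1$ — no net volume change — while stretching two-fold along one axis
and halving along another. The stretches and ADG make that visible.

### Why Lagrange strain, and not polar decomposition

Decomposing $F$ into rotation and stretch treats shear as rotation of a
rectangular element and cannot represent genuinely three-dimensional
shearing. $E$ retains the full quadratic term $F^\top F$, so shear appears
explicitly in the off-diagonal components and rigid rotation produces no
strain at all; both properties are tested. Eulerian strain measures and
stress estimation (which would need tissue constitutive properties) are out
of scope.

## Numerical choices

**Derivatives.** The derivative scheme is not dictated by the model, so the
package uses the standard second-order choice: central differences on
interior voxels, in physical mm, with the output mask eroded by one voxel so
every reported voxel has a complete stencil. `scheme = "forward"` is
available when a one-voxel erosion is unacceptable (thin masks), at
first-order accuracy. Central differences reproduce affine displacement
fields to machine precision and converge at second order on smooth fields —
halving the spacing on the Gaussian-expansion phantom divides the maximum
JD/strain error by $\approx 3.8$ (the acceptance script recomputes this at
$32^3$, 2 mm vs $64^3$, 1 mm).

**Units and orientation.** NIfTI has no convention for whether vector
volumes store mm or voxel offsets, so the reader takes an explicit `units`
flag and converts voxel offsets through the affine's linear part. Grids must
be axis-aligned RAS (diagonal positive linear part); non-axis-aligned inputs
are refused rather than silently reoriented, since reorienting a third-party
deformation field is a registration-level operation the package deliberately
does not perform.

**Eigenvalues.** Strain eigenvalues are computed per voxel with LAPACK's
symmetric solver — machine precision, at roughly 20 µs/voxel, which covers a
$64^3$ grid in a few seconds. Per-voxel identities ($\det F = \lambda_1
\lambda_2 \lambda_3$, $\mathrm{tr}\,E = \tfrac12(\sum \lambda_i^2 - 3)$)
hold to $10^{-10}$ or better and are asserted in the tests.

**Degenerate voxels.** Voxels with $JD \le 0$ (folding), $e_i \le -\tfrac12$
(no real stretch) or $|2E_{ij}| > \lambda_i \lambda_j$ (non-physical shear)
are counted, reported in the QC summary, and excluded from the propagated
mask so they never enter statistics. The ADG normalisation constant
$\sqrt{3/2}$ (the usual fractional-anisotropy constant) is recorded in the
QC metadata; applying the anisotropy formula to strain eigenvalues instead
of stretches is available via `adg_on = "strain"` but is not the default,
because the stretches are the growth-rate quantity the index is meant to
summarise.

## Interval normalisation, warping, smoothing

Scan intervals differ across subjects, so per-interval parameters are
rescaled to a common 90-day (3-month) scale by the factor $90/\text{days}$.
For strains and angles the null value is 0 and plain scaling is correct. For
JD the null is 1, and scaling JD itself would move the null; the default is
therefore the offset form $JD_\text{adj} = 1 + (JD - 1)\cdot 90/d$, which
preserves the one-sample null exactly. Direct scaling is kept behind
`mode = "direct"` for comparison. The adjustment is stamped into the map's
metadata and a second application is an error.

Parameter maps are brought to a common space by resampling through supplied
deformation fields (the package never estimates registrations): trilinear
interpolation for scalar/tensor values, nearest-neighbour for labels. Tensor
components are resampled componentwise, without reorientation by the local
rotation — a deliberate simplification, acceptable because all downstream
statistics treat components marginally.

"Minimal smoothing" is implemented as a single 6-neighbour
anisotropic-diffusion pass with Perona–Malik weights
$\exp(-(\Delta/\kappa)^2)$ and step $1/6$; $\kappa$ defaults to the 90th
percentile of in-mask neighbour differences. The pairwise flux is
antisymmetric, so the in-mask total is conserved; a constant map is a fixed
point, a plateau two voxels from an edge is untouched after one pass, and no
new extrema can appear.

## Statistics

**One-sample tests.** At each voxel, growth is tested against the no-growth
null ($JD = 1$, strain $= 0$) with a two-sided one-sample t-test
($df = n - 1$). Sidedness is not dictated by the scientific question in an
obvious direction (contractions are as interesting as expansions), so
two-sided is used throughout. Zero-variance voxels get $p = 1$ at the null
and are flagged otherwise, avoiding infinite t.

**FDR.** Multiple comparisons are handled with Benjamini–Hochberg at
$q = 0.05$, applied within each parameter map separately (per parameter, per
interval) rather than pooled across intervals. Adjusted p-values come from
`stats::p.adjust`; the rejection set is the step-up set, equivalently
adjusted $p \le q$, and the tests check it against a brute-force search over
all rejection thresholds.

**Age model.** Age effects are estimated with a linear mixed model
$y_{ij} = \beta_0 + \beta_1\,\text{age}_{ij} + b_i + \varepsilon_{ij}$, with
a random intercept per subject, fitted by REML. The implementation profiles
the criterion down to the single variance ratio
$\gamma = \sigma_b^2/\sigma_e^2$: for fixed $\gamma$ the GLS solution and
residual variance are closed-form (block-diagonal covariance, one block per
subject), and $\gamma$ is found by 1-D minimisation on the log scale with
the $\gamma = 0$ boundary checked explicitly. This keeps the voxel-wise loop
deterministic and fast (~1–2 ms per voxel). The fit agrees with
`lme4::lmer` to better than $10^{-4}$ relative on fixed effects and variance
components (tested on 20 random datasets). Wald t-tests for the fixed
effects use $df = n_\text{obs} - n_\text{subjects} - \mathrm{rank}(X) + 1$,
a between–within allocation; at the cohort sizes this model targets
(dozens of subjects, $\ge 2$ intervals each) the choice of df convention is
immaterial, and simulated 95% CI coverage lands near nominal.

**ROI classification.** Region means are arithmetic means over in-mask
voxels. A region is "fast" growing if its mean exceeds the 75th percentile
of the parameter over *all* in-mask voxels (whole brain, not region means),
"slow" below the 25th. Percentiles use linear interpolation between order
statistics (`quantile` type 7), which is permutation-invariant; the
thresholds are attached to the output table.

## The synthetic-data generator

The package is validated entirely against synthetic inputs with known
truth, at two levels.

*Analytic deformations* (affine, rigid rotation, simple shear, uniform
scale, Gaussian radial expansion) expose closed-form $u(X)$ and $F(X)$, so
the whole strain pipeline can be checked against exact oracles. The Gaussian
expansion $u = \alpha\, e^{-\|d\|^2/2\sigma^2} d$ (with $d = X - c$) is the
smooth nonlinear test case; its default $\alpha = 0.3$ gives a maximum
stretch $\approx 1.3$, comparable to the strain magnitudes seen in rapidly
growing infant cortex, and the constructor refuses amplitudes that would
fold ($JD \le 0$).

*Simulated cohorts* draw per-(subject, interval) parameter maps from the
same generative model the statistics assume:
$y_{ij}(v) = \beta_0 + \beta_1\,\text{age}_{ij}\,\text{blob}(v) + b_i +
\varepsilon_{ij}(v)$. The default schedule emulates a first-year infant
design — 33 subjects, scans at mean ages 26, 102, 189, 279 and 372 postnatal
days, hence four intervals with midpoint ages (64, 145.5, 234, 325.5) days
and lengths (76, 87, 90, 93) days. The "blob" mask localises the age effect
for sensitivity/specificity checks; $\beta_1 = 0$ gives a global null for
FDR calibration. Generators are pure functions of (spec, seed).

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: registration error and its spatial
correlation, spatially correlated residual noise (voxel noise is i.i.d., so
FDR calibration here says nothing about cluster-level behaviour),
tissue-dependent variance, motion artefacts, or atlas misalignment. The
statistical checks validate the estimator and its calibration under the
model's own assumptions, not the upstream imaging chain.

## Problem sizes

Test and acceptance workloads run at desk scale, chosen once: $8^3$–$10^3$
grids for exactness checks (the checked properties are grid-size-invariant),
$32^3 \to 64^3$ for the convergence ratio, 10,000 voxels for type-I-error
calibration, 200 replicates of the 33-subject cohort for REML recovery, and
20 replicates of a 16³ phantom null cohort for FDR control. The pipeline
itself has no intrinsic size limit; a $64^3$ full strain computation takes a
few seconds.

## Known limitations

* No registration, segmentation, or deformation-field estimation: fields are
  inputs, and their quality bounds everything downstream.
* No tensor reorientation during warping.
* Grids must be axis-aligned RAS.
* The mixed model is exactly the random-intercept form — no random slopes,
  no covariates beyond age.
* ROI classification is a descriptive quartile rule, not an inferential
  procedure; it inherits the arbitrariness of the 25/75 thresholds.
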