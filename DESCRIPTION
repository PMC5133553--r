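Package: strainmorph
Title: Finite-Strain Tensor-Based Morphometry for Longitudinal Brain Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-wise finite-strain analysis of longitudinal deformation
    fields. From per-interval 3-D displacement fields the package computes the
    deformation gradient, Jacobian determinant (local volume change), Lagrange
    strain tensor (directional normal and shear strains), principal stretches,
    a fractional-anisotropy-style index of directional growth, and shear
    deformation angles. Downstream statistics include interval normalisation
    to a common 90-day scale, warping of parameter maps to a common space,
    edge-preserving smoothing, voxel-wise one-sample tests with
    Benjamini-Hochberg false discovery rate control, a random-intercept
    linear mixed-effects model for age effects fitted by profiled REML, and
    percentile-based classification of fast and slow growing atlas regions.
    A synthetic-data module provides analytic deformations with closed-form
    strain oracles, phantom atlases, and simulated longitudinal cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
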