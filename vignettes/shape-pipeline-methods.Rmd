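---
title: "Methods: landmark shape analysis of crania and mandibles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark shape analysis of crania and mandibles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skullmorph)
```

This vignette documents the statistical machinery in `skullmorph`, the
assumptions behind each stage, the tunable parameters, and the design
choices made where several defensible options existed. It is written for
users who want to judge whether the pipeline's defaults fit their data,
and for maintainers who need to know why the code does what it does.

## Data model

A specimen is a configuration of *k* homologous 3D landmarks in
millimetres with a missingness mask (`landmark_set`). Crania and mandibles
are analysed as entirely separate datasets end to end; nothing in the
package ever pools them. Bilateral (object) symmetry is described by a
`symmetry_scheme`: a partition of the landmarks into left/right pairs and
midline points, 1-based, stored on disk as editable YAML. The schemes
shipped in `inst/extdata/` are synthetic: they carry the conventional
counts (39 cranial, 33 mandibular landmarks) and the pairing structure,
not real anatomical definitions, and should be replaced by the user's
digitization protocol.

## Missing-landmark estimation

Specimens with 20% or more missing landmarks are excluded (strict `<`
threshold in `filter_missingness`; the inclusion rule is evaluated on the
raw mask, before any estimation). The remaining gaps are filled in two
ordered passes, mirroring standard osteometric practice:

1. **Mirror-imaging** (`impute_mirror`): a missing bilateral landmark with
   a present antimere is replaced by the antimere's reflection across the
   midsagittal plane. The plane is fitted by total least squares to the
   points that must lie on it — present midline landmarks and midpoints of
   complete pairs — which uses all the symmetry information at once and
   degrades gracefully. When those points do not span a plane (fewer than
   three, or nearly collinear) the normal falls back to the principal axis
   of the left–right difference vectors, which is parallel to the true
   normal for a symmetric object. The conditioning test is a relative
   eigenvalue gap (second scatter eigenvalue above 1e-10 of the first).
2. **Thin-plate-spline interpolation** (`impute_tps`): midline landmarks
   and pairs missing on both sides are mapped from a complete reference
   through the 3D TPS with kernel U(r) = −r (conditionally positive
   definite under the affine side conditions, so bending energy is
   nonnegative and zero exactly for affine maps). The reference is the
   Procrustes mean of fully complete specimens of the same group when at
   least three are available, otherwise of all complete specimens; one
   single estimation pass, no EM-style iteration. TPS is exact at its
   constraints, affine-exact, and scale-adaptive, so the reference's
   overall scale is immaterial.

Imputed landmarks are recorded per specimen (`imputation_provenance`) and
then treated identically to observed ones in every downstream statistic.
Multiple imputation and uncertainty propagation are out of scope.

`intra_observer_error` supports repeatability studies (replicate
digitizations of the same specimens): per-landmark mean Euclidean
deviation from the replicate centroid. For isotropic digitization noise
with per-axis SD σ and r replicates its expectation is
2√(2/π)·σ·√(1−1/r), the closed form the tests check against; a grand mean
near 0.8 mm is a typical craniometric repeatability figure and is the
noise scale the simulator emulates.

## Superimposition and the symmetric component

`gpa` performs full generalized Procrustes analysis: translate to a common
centroid, scale to unit centroid size (CS is retained separately, in mm,
as the size variable), and iteratively rotate each configuration to the
evolving mean until the total Procrustes sum of squares decreases by less
than `tol` (default 1e-10, `max_iter` 200 — fully random shape samples sit
in the slowest, nearly isotropic regime and may need a few hundred more
sweeps, so the limit is a user parameter). Rotations come from the SVD
with the determinant forced to +1: reflections are never allowed in
superimposition — biological handedness must be preserved — and the sign
ambiguity at a zero singular value is resolved deterministically by
flipping the axis with the smallest singular value.

Two presentation choices make results reproducible and comparable across
runs: the final mean shape is rotated into a canonical orientation
(principal axes, signs fixed by third moments along each axis, det +1), so
tangent coordinates are invariant to arbitrary rigid motion and scaling of
the inputs and to input order; and all eigenvector signs downstream follow
the largest-loading-positive convention.

Aligned shapes are projected orthogonally onto the subspace orthogonal to
the mean-shape direction (`tangent_project`), the usual linearization of
shape space that makes multivariate statistics legitimate; the projection
is idempotent and accurate to second order for the small shape distances
typical of within-species cranial data.

`symmetrize` extracts the symmetric component of each aligned shape: the
reflected, relabeled copy is superimposed back onto the original by a
proper rotation and the two are averaged. The output is exactly symmetric
under the scheme's reflection–relabel map (the alignment rotation of the
average is the same one that aligned the copy, a fixed-point property the
tests verify to 1e-10). Because averaging shrinks centroid size slightly,
the pipeline re-runs GPA on the symmetric shapes before any statistics —
whether the original study re-superimposed after symmetrization is not
knowable from its description, and re-running is the cleaner choice since
it restores the unit-size invariant.

## Ordination, group statistics, trees

* **Total PCA** (`total_pca`): eigendecomposition of the sample covariance
  of tangent coordinates. Downstream statistics use the smallest set of
  leading PCs jointly reaching 95% cumulative variance
  (`retain_for_variance`, threshold configurable), capped where necessary
  so the within-group covariance stays invertible (q ≤ n − g − 1).
* **Between-group PCA** (`between_group_pca`): axes are eigenvectors of
  the covariance of group mean vectors, weighted by group size by default
  (`weighted = FALSE` gives every group equal weight); all specimens are
  projected. With g groups at most g − 1 eigenvalues are nonzero. Because
  the variance share of an axis can be quoted against either denominator,
  both are reported: `variance_fraction` (relative to between-group
  variance) and `total_variance_fraction` (relative to total specimen
  variance). No cross-validated correction for bgPCA's known optimism is
  applied; interpret separation on these axes accordingly.
* **Size and shape tests**: `size_anova` and `tukey_hsd` wrap the standard
  one-way ANOVA and Tukey–Kramer HSD on centroid size. `shape_manova` uses
  Wilks' Λ with Rao's F approximation (the most common default in this
  workflow) and reports an effect size. The "coefficient of determination"
  of a MANOVA has no single standard formula; the default here is the
  trace ratio tr(B)/tr(T) of the between and total SSCP matrices of the
  retained scores, with 1 − Λ available via `r2_method = "wilks"`. The two
  coincide in the univariate case. The pipeline evaluates the usual
  sensitivity rows: all cultural groups, without the most divergent group,
  dietary groups, hunter-gatherers versus all farmers combined, and
  farmers only.
* **Allometry** (`allometry_regression`): OLS of each retained PC score on
  centroid size — raw CS by default, taken literally from the field's
  usual phrasing; log-CS via `log_cs = TRUE`. The multivariate summary is
  the trace of the predicted-score covariance over the trace of the total
  score covariance.
* **Mahalanobis distances** (`mahalanobis_matrix`): pooled within-group
  covariance with the unbiased divisor n − g; distances reported
  unsquared.
* **Neighbor-Joining** (`neighbor_joining`): Saitou–Nei agglomeration,
  written out in the package because the deterministic tie-break
  (lexicographically smallest pair at equal Q) and the negative-length
  policy are part of the contract; `ape` serves as container, Newick
  serializer, and independent cross-check in the tests. Negative branch
  lengths on non-additive input are reported as-is and flagged —
  transparency over cosmetics. On additive matrices the tree metric
  reproduces the input exactly.
* **Bootstrap supports** (`bootstrap_supports`): specimens are resampled
  with replacement within groups — the only resampling unit that preserves
  the group structure the tree describes — and total PCA, 95% retention,
  and Mahalanobis distances are recomputed per replicate (1000 by
  default). GPA is treated as fixed preprocessing and not re-run per
  replicate; re-aligning each bootstrap sample would change supports only
  at second order while costing two orders of magnitude more time.
  Replicates with singular covariance are skipped and counted, with a
  warning past 5%. Supports are the percentage of valid replicate trees
  containing each internal-edge bipartition of the observed tree, and are
  reproducible given a seed.

## The synthetic generator

`synthetic_design`/`simulate_dataset` generate data with exactly the
structure the analysis assumes, so ground truth is available in closed
form. A specimen in group g is

> size × R(template + effect_g + symmetric noise + asymmetric noise) + t

with: an exactly symmetric template on a half-ellipsoid (centroid size 150
mm, the cranial scale); group mean-shape displacements specified in
tangent space, symmetrized and orthogonalized against translation and the
template direction so that the generating Mahalanobis distance between
groups is ‖effect_g − effect_h‖ / shape_noise_sd; isotropic Gaussian
tangent noise (projection onto the symmetric or asymmetric subspace keeps
the per-direction SD, so the nominal SDs apply directly within each
subspace); log-normal centroid size; a random rigid motion per specimen;
and MCAR missingness capped below 20% by rejection (the weakest
missingness assumption, since no mechanism is known).

Default parameters describe the study conditions the package is aimed at:
five groups of 8/10/28/13/10 crania; a strongly displaced hunter-gatherer
group (effect 0.06 Procrustes units = 6 within-group SD) against mildly
separated farmer groups (0.008–0.015); within-group shape SD 0.01
Procrustes units per coordinate; fluctuating asymmetry 0.004; log-size SD
0.03 with the displaced group ~5% larger; 5% missingness. At centroid size
150 mm the digitization-scale component of the noise corresponds to
sub-millimetre landmark deviations, consistent with a 0.8 mm repeatability
figure.

What the generator does **not** emulate: anatomically realistic skull
geometry, correlated (non-isotropic) biological variation, directional
asymmetry, allometric shape–size covariance (the true allometric slope is
zero unless configured), measurement error that differs by landmark type,
and non-random missingness. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
every property of real material.

## Numerical choices and problem sizes

Interpolation and orthogonality tolerances follow the magnitudes the
linear algebra supports: TPS residuals at constraints ≤ 1e-8,
superimposition identities at 1e-10–1e-12, Monte-Carlo checks at bands
matched to their simulation error. The test suite exercises GPA invariants
on 50 random datasets (n = 30, k = 39), type-I-error calibration of MANOVA
and ANOVA on 1000 null simulations (three groups of 20), Mahalanobis
recovery at n = 200 per group averaged over three simulation replicates
(Monte-Carlo SD of a single replicate is ~8%, which would dominate a 15%
accuracy statement), NJ consistency on additive matrices up to 8 taxa
against brute-force enumeration with nonnegative least-squares branch
lengths (unconstrained least squares can prefer degenerate topologies with
negative internal edges on non-additive input), and a 1000-replicate
bootstrap of the realistically sized design. These sizes were chosen so
each property is measured well while the whole suite stays quick to run.

## Known limitations

No sliding semilandmarks, no Procrustes ANOVA/permutation MANOVA, no
discriminant classification, no outgroup rooting, no correction for
bgPCA's spurious-separation tendency, single imputation only. The MANOVA
effect size depends on the chosen definition (trace ratio vs 1 − Λ); both
are computed, and comparisons across studies should say which one they
quote.
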