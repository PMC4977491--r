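# skullmorph

3D landmark-based geometric morphometrics for bilaterally symmetric
skeletal structures, built for biodistance studies that compare crania and
mandibles across archaeologically defined groups (cultural horizons,
dietary regimes). It implements the complete analysis chain that such
studies run: missing-landmark estimation, generalized Procrustes analysis
with the symmetric component of shape, size and shape statistics,
between-group ordination, Mahalanobis biodistances, and bootstrapped
Neighbor-Joining trees — plus a synthetic landmark generator with known
ground truth so every stage can be validated without access to original
scan data.

## The methods in brief

Given *n* specimens with *k* homologous 3D landmarks each (conventionally
k = 39 for crania, k = 33 for mandibles), the pipeline:

1. **Estimates missing landmarks.** Bilateral landmarks with a present
   antimere are reflected across the midsagittal plane (total-least-squares
   fit to midline landmarks and pair midpoints). The remainder — midline
   points and pairs missing on both sides — are mapped from a complete
   reference by a 3D thin-plate spline with kernel U(r) = −r, the smooth
   interpolant minimizing bending energy. Specimens missing ≥ 20% of
   landmarks are excluded.
2. **Superimposes shapes.** Generalized Procrustes analysis: configurations
   are centered, scaled to unit centroid size CS = √Σᵢ‖xᵢ − x̄‖², and
   iteratively rotated to the evolving mean by least squares; aligned shapes
   are projected into the tangent space at the mean. The **symmetric
   component** of each shape — the average of the configuration and its
   optimally aligned reflected-relabeled copy — feeds all downstream
   statistics, removing asymmetry.
3. **Tests size and shape.** One-way ANOVA and Tukey HSD on centroid size;
   total-variance PCA with the leading components jointly explaining 95% of
   variance retained; MANOVA (Wilks' Λ, Rao's F) with a trace-based effect
   size R² = tr(B)/tr(T) over the configured grouping schemes; per-axis and
   multivariate allometric regression of PC scores on centroid size.
4. **Ordinates and clusters groups.** Between-group PCA (eigenvectors of
   the size-weighted covariance of group mean shapes, all specimens
   projected); Mahalanobis distances D(i,j) = √((m̄ᵢ−m̄ⱼ)ᵀW⁻¹(m̄ᵢ−m̄ⱼ)) from
   the pooled within-group covariance; Saitou–Nei Neighbor-Joining on D with
   specimen-level stratified bootstrap supports (default 1000 replicates).

## Worked example

Simulate a five-horizon cranial study (group sizes 8/10/28/13/10, one
strongly displaced hunter-gatherer group, digitization-scale noise) and run
the full pipeline:

```r
library(skullmorph)

design <- synthetic_design(seed = 1)       # 39 landmarks, 5 groups, n = 69
sim    <- simulate_dataset(design)
res    <- run_pipeline(sim$sets, design$scheme,
                       bootstrap_reps = 1000, seed = 2)
res
#> pipeline_result: 69 specimens (0 excluded for missingness), 5 groups
#>   size ANOVA: F = 7.456, p = 5.391e-05
#>   PCs retained at 95% variance: 39
#>   bgPC1: 60.5% of between-group, 8.8% of total variance
#>   MANOVA:
#>  grouping                    subset  r_squared      p_value
#>  cultural               all samples 0.12447350 6.710889e-05
#>  cultural        without Mesolithic 0.05857084 2.374397e-02
#>   dietary    all groups (HG, EF, F) 0.08991560 1.234373e-04
#>   dietary  farmers combined (HG, F) 0.07596586 2.027497e-06
#>   dietary without HG sample (EF, F) 0.01684369 2.919128e-01
#>   Mahalanobis distances:
#>            A-group C-group Meroitic Mesolithic Pharaonic
#> A-group      0.000   4.751    5.271     11.905     5.355
#> ...
#>   NJ tree: (C-group:1.293,(Mesolithic:7.397,Pharaonic:1.59)68:0.716,...
#>   allometry: multivariate R^2 = 0.0223
```

Reading the output: centroid size differs significantly between groups
(ANOVA F = 7.46); the displaced group separates on the first between-group
PC; cultural group membership explains ~12% of shape variation (MANOVA
trace R², p ≪ 0.01) and much less once the displaced group is dropped; the
displaced group is by far the most distant in Mahalanobis terms and
carries the longest terminal branch in the NJ tree; allometry is negligible
(R² ≈ 0.02). `run_pipeline(..., output_dir = "out")` additionally writes
the report bundle: TSV tables, PC scores, Newick tree with bootstrap
supports, mean shape as TPS, and a JSON run log with seed and per-stage
checksums.

Real data enter the same way through `read_tps()` / `read_landmark_csv()`
and a YAML symmetry scheme (`read_symmetry_scheme()`; editable example
schemes ship in `inst/extdata/`), or entirely from a YAML configuration via
`run_pipeline(config = "config.yaml")`.

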