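---
title: "Methods: quantifying wing shape change across metamorphosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying wing shape change across metamorphosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

## The problem

The adult *Drosophila* wing develops from the larval wing imaginal disc
through a dramatic metamorphic transformation: the disc folds along the
dorso-ventral (D/V) boundary, everts, and the blade elongates along the
proximo-distal axis. To locate *when* in development a genetic variant
changes the final wing, one needs homologous measurements of the same
structure at each stage. Protein expression domains (Cubitus
interruptus, Delta) mark the proveins and the D/V boundary in larval
discs and early pupal wings, letting the same 8 landmarks and 9
semilandmarks be placed on third-instar discs, 5 h pupal wings, and
adult wings. `wingmorph` implements the full quantitative pipeline over
such data: ingestion, superimposition, multivariate testing, outlier
screening, scalar measures and ratio comparisons — plus a synthetic-data
generator so every stage is testable offline.

## Data model

A specimen is a 17 x 2 landmark matrix in mm. Landmarks 1, 3, 5, 7 lie
on the D/V boundary / wing margin at proveins L1, L3, L4, L5; landmarks
2, 4, 6, 8 mark their proximal ends. Semilandmarks 9–14 follow the
margin between landmarks 1 and 3, semilandmarks 15–17 between 5 and 7.
Semilandmarks carry information only perpendicular to the margin; their
tangential position is arbitrary and is slid during alignment.
Stage (larva / pupa / adult), genotype (yw wild-type, ds, shf2 by
default; arbitrary labels allowed) and sex ride along as metadata.

## Superimposition

`gpa()` performs generalized Procrustes analysis on all specimens
jointly (all stages and genotypes together): center, scale to unit
centroid size, rotate each configuration onto the running consensus by
rotation-only least squares (reflections never allowed — all wings share
handedness), update the consensus, and iterate until the consensus moves
less than `tol = 1e-10` (at most 100 iterations; non-convergence is
flagged, not thrown). Because the GPA fixed point is only defined up to
rotation, output orientation is pinned deterministically: the consensus
principal axis is rotated onto the x axis, with a sign rule on landmark
1. This makes every downstream table reproducible across runs and input
orders.

### Semilandmark sliding

The sliding criterion is **chord-tangent projection against Procrustes
distance**: each semilandmark moves along the chord between its flanking
points (anchors included) to the foot of the perpendicular from the
corresponding consensus point, then the dataset is re-registered, and
the two steps alternate. The classical alternative is bending-energy
sliding; with only 9 semilandmarks in two short runs the
Procrustes-distance criterion is better conditioned, so it is the
documented default (`mode = "none"` disables sliding entirely). Two
numerical choices matter:

* Each outer iteration is accepted only if the total Procrustes sum of
  squares did not increase, so the objective is non-increasing by
  construction (an increasing step is rolled back and iteration stops).
* Iterations are capped (default 10). With strongly heterogeneous
  groups the consensus keeps drifting and unbounded sliding lets
  semilandmarks creep along the margin, absorbing real between-stage
  signal; the cap trades a little residual tangential variance for
  stability. A practical consequence: a mean-shape *difference* that is
  tangential to the margin is partly removed by sliding, which is why
  the effect-recovery check in the test suite estimates genotype effects
  on the unslid alignment.

### Degrees of freedom

17 landmarks x 2 coordinates − 4 similarity parameters − 9 sliding
constraints = 21 shape dimensions. A historical convention in this
literature quotes 18; we do not force that. Because chord sliding
removes tangential variance only approximately (and is capped), the
empirical covariance rank is computed, and the test suite asserts that
less than 5% of total variance lies beyond 21 axes after sliding rather
than asserting an exact rank. `manova_wilks()` reports the df actually
used.

### Tangent-space adequacy

`tangent_check()` correlates all-pairs Euclidean distances of the
registered coordinates with all-pairs Procrustes distances. Despite the
large larva-to-adult shape differences, this correlation is ~0.9999 on
default synthetic data, so linear multivariate statistics in the tangent
space are justified.

## Ordination and testing

`shape_pca()` is an ordinary covariance eigen-decomposition with a
deterministic sign convention (largest-magnitude loading positive);
18 axes are retained by default for downstream analyses. `cva()`
maximizes between- over within-class scatter and spheres the canonical
scores (pooled within-class covariance = identity).

### Randomization MANOVA

Shape variance differs strongly among stages, violating the homogeneity
assumption of parametric MANOVA across stages. The package therefore
tests genotype and stage-by-genotype effects by randomization. Each
observation is decomposed as

    S = grand + R_stage + R_genotype + R_cell + eps

where the marginal means are unweighted means of cell means by default
(the Type III spirit, appropriate for the unbalanced design; an
observation-weighted option exists) and the reconstruction is exact.
Randomized datasets rebuild each observation with the component under
test **plus the individual deviation** permuted among individuals
(genotype: `R_genotype + eps`; interaction: `R_cell + eps`), everything
else held fixed, and Wilks' Λ = det(E)/det(E+H) recomputed for the same
Type III effect.

Two design points deserve emphasis, both found during calibration:

* Permuting the residual-mean component *alone* produces null datasets
  whose genotype means lack the sampling noise present in the observed
  statistic; the empirical type-I error of that literal scheme is ~1.0.
  Bundling `eps` makes the observed dataset the identity member of the
  permutation family, and the test calibrates (type-I ≈ 0.05, asserted
  by the acceptance suite at n_rand = 200 over 200 null datasets).
* Permutations are **within stages** by default. Permuting across all
  individuals under stage-heteroscedastic noise gave type-I ≈ 0.15; the
  within-stage scheme preserves each stage's variance. The across-all
  variant remains available for the genotype effect and is recorded in
  the result object.

p-values use the add-one estimator `(1 + #{null ≤ observed}) /
(n_rand + 1)`; the convention is 1000 randomizations.

## Outlier screening

Outliers are diagnosed within each genotype-by-stage group on the first
5 pooled shape PCs with the Minimum Covariance Determinant estimator
(backed by `MASS::cov.rob`, maximal-breakdown support fraction
`ceiling((n + p + 1)/2)/n` by default), so that outliers cannot inflate
the covariance used to judge them. Raw robust Mahalanobis distances from
a 5-dimensional MCD fit are *not* on an SD-like scale: for clean
Gaussian groups of n = 50, ~25% of specimens exceed "3" (the chi_5 tail
at 3 is already 10.9%, and finite-sample MCD inflates distances
further). The reported `robust_distance_sd` is therefore a robust
z-score of the group's own distance distribution,
`(d − median(d)) / mad(d)`, which is affine-invariant, breakdown-safe,
and false-flags <5% of clean specimens at the 3-SD rule (asserted by the
acceptance suite over 2000 simulated groups). Raw-distance and
chi-square-quantile conversions are available via `units=`. Flags at 3
(putative outlier, re-examine) and 6 SD (candidate for omission) are
reported; **nothing is ever dropped automatically** — exclusions are an
explicit id list in the pipeline config, mirroring manual re-inspection
practice. One caution: the false-flag calibration holds for groups
appreciably larger than the number of screened axes (it is asserted at
n = 50); at the study's smallest group sizes (n = 6–16 with 5 axes) the
median/MAD scale estimate is noisy and the 3-SD rule over-flags — one
more reason flags mean *review*, never removal. Univariate size
screening uses Grubbs' test with the exact t-quantile critical value.

## Scalar measures

All shape-type scalars are computed on configurations standardized by
centroid size (division by `sqrt(sum((x - centroid)^2))`), making them
dimensionless and similarity-invariant:

* the 28 pairwise distances between the 8 fixed landmarks
  (`stlen12`…`stlen78`);
* anterior (1, 9–14, 3) and posterior (5, 15–17, 7) margin polyline
  lengths.

Region areas use the surveyor's (shoelace) formula over fixed,
documented vertex orders: anterior 2,1,9–14,3,4; middle 4,3,5,6;
posterior 6,5,15–17,7,8; total 2,1,9–14,3,5,15–17,7,8,6 (the 3→5 margin
gap bridged by the chord). Only the vertex *sets* are conventional; the
orders were fixed once so the paths are simple on wing-like
configurations, and simplicity is checked at run time (a
self-intersecting path warns with the signed area). Areas are emitted
both raw (mm², feeding size ratios) and standardized (dimensionless,
feeding shape-type comparisons); the two variants answer different
questions and are clearly named. Note the total polygon is not the union
of the three sub-polygons (the proximal boundary differs), so
`area_total >= sub-area` is not an invariant.

### Ratio comparisons

Stage-to-stage and genotype-to-genotype changes are summarized as ratios
of group means. Specimens are destructively sampled (a wing is measured
at one stage only), so there is no pairing and the point estimate is
`mean(numerator group) / mean(denominator group)`. Uncertainty comes
from a bootstrap in which **both** groups are independently resampled
with replacement at their own sizes in every replicate (1000 by
convention), with a 2.5–97.5 percentile interval. A known limitation,
measured by the acceptance suite: at n = 15 per group the percentile
interval covers the true ratio ≈ 92–93% of the time, not 95% — the
usual small-sample undercoverage of percentile intervals. The interval
is reported as specified; users needing calibrated coverage at such
sizes should enlarge groups or use a studentized interval (out of
scope here). Delta-method standard errors for area ratios assume zero
covariance between stages (true under destructive sampling), which makes
cross-ratio tests conservative. Factorial fixed-effects models for
scalar traits (stage, genotype, sex) use Type III F tests under
sum-to-zero contrasts, drop interactions with P > 0.2 (highest order
first) and adjust pairwise genotype contrasts on least-squares means by
the Tukey–Kramer method; areas are analyzed on log10 scale.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, not the biology that produces it:

* **Templates.** Three hard-coded 17-point outlines (near-circular
  larval pouch; paddle-shaped pupal wing; elongated adult blade with a
  contracted proximal base). Their parameters were chosen once so that
  between-stage template Procrustes distances (0.50 / 0.28 / 0.72 for
  larva–pupa / pupa–adult / larva–adult) approximate the reported
  between-stage mean shape distances. They are fixtures, not estimates
  of the real mean shapes.
* **Genotype effects.** Column-centered 17 x 2 displacements added to
  the stage template: the ds-like pattern contracts the distal wing
  along the proximo-distal axis at the larval stage and broadens the
  wing antero-posteriorly from the pupal stage on; the shf2-like pattern
  pulls the L3/L4 landmark pairs together at every stage. Magnitudes per
  stage (ds 0.086/0.136/0.105; shf2 0.116/0.129/0.067 centroid-size
  units) are derived from the reported within- vs between-genotype mean
  distance tables.
* **Noise.** Isotropic Gaussian per coordinate, per stage
  (SD 0.012 / 0.029 / 0.0035 shape units), calibrated so aligned
  within-genotype mean pairwise distances come out ≈ 0.11 / 0.17 / 0.03
  with the prescribed ordering pupa > larva > adult.
* **Size.** Each configuration is scaled so its total polygon area
  follows a lognormal law with the reference per-group mean and CV
  (`area_reference()`, the published sampling design: 108 wings over 9
  stage-genotype groups).
* **Outliers.** `inject_outliers()` displaces chosen specimens in a
  uniformly random direction of the 34-dimensional shape space with norm
  `displacement_sd x noise SD x sqrt(34)`, returning ground-truth ids.

What the generator deliberately does **not** emulate: correlated
(non-isotropic) within-group covariance, digitization bias along the
margin, sex effects on shape, or stage-dependent landmark homology
error. Isotropic noise at the calibrated pupal level is large relative
to semilandmark spacing, so some simulated margins zigzag and a fraction
of total-outline polygons self-intersect — real digitized margins do
not, and the per-specimen simplicity warning exists precisely to make
this visible. Consequently a green test establishes that the *pipeline
mathematics* behaves as specified under the stated sampling design — not
that the pipeline was validated against real wing images.

## Determinism

Every stochastic step takes an explicit seed (simulation, permutation,
bootstrap, MCD subset search through R's RNG); the pipeline derives all
sub-seeds from the single config seed, and `run_pipeline()` with the
same config writes byte-identical CSVs whose headers carry a hash of the
config. Generation order over groups is fixed, so datasets are pure
functions of the seed.

## Known limitations

* Chord (Procrustes-distance) sliding, not bending energy; capped
  iterations (see above).
* Percentile bootstrap undercoverage at small n (see above).
* 2-D landmarks only; no curve resampling or image processing.
* Parametric MANOVA p-values (Rao's F) are provided for within-stage
  tests only in spirit: across stages, use the randomization test.
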