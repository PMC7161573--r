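---
title: "Quantifying intraspecific shape variation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intraspecific shape variation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Comparative studies of skeletal structures — here, the cochlea of toothed
whales — routinely represent each species by a single specimen, because
museum material and scanning time are scarce. Whether that is safe depends
on an assumption that is rarely testable: that variation *within* a species
is small relative to variation *among* species. morphovar packages the full
analysis needed to test that assumption when one species can be sampled
deeply (say, 18 conspecific specimens) against a broad single-specimen
sample of other species: superimposition of curve-structured 3D landmarks,
ordination, dispersion statistics, group tests, and an exhaustive
subset-sensitivity design that asks how many conspecific specimens are
needed before the among-species signal stabilises.

## Superimposition

Shapes enter as configurations of `p` ordered 3D landmarks, many of which
sample curves as sliding semilandmarks. Generalised Procrustes Analysis
(`gpa()`) removes position, scale and orientation:

1. every configuration is centred and scaled to unit centroid size (the
   square root of summed squared distances to the centroid);
2. the reference is initialised to the first specimen; each specimen is
   rotated to the reference by the proper (det = +1) rotation from the
   singular value decomposition of the cross-covariance;
3. the reference is updated to the coordinate-wise mean and the pass
   repeats until the total Procrustes sum of squares changes by less than
   `tol` (default 1e-9) or `max_iter` (default 100) passes.

Specimens stay at unit centroid size throughout (partial Procrustes); the
reported consensus is the coordinate-wise mean of the aligned specimens.
The recorded objective trace starts after the first rotation pass, from
which point each pass is a joint minimisation step, so the trace is
non-increasing by construction.

Two choices deserve comment:

* **Reflections are never allowed.** Cochleae are chiral, and a
  superimposition that silently mirrored a specimen would manufacture
  false similarity. Specimens from the other side of the head are instead
  standardised explicitly with `mirror()`; the pipeline default mirrors
  right-side specimens onto the left (`mirror_side = "right"`) whenever the
  metadata records sides. This is a reversible convention, not a claim
  about the data: side is also available as a covariate test so its effect
  can be measured rather than assumed.
* **The consensus is the sliding and alignment reference.** Using a
  designated specimen instead would make results depend on input order;
  the similarity-invariance tests verify order effects vanish at
  convergence.

## Sliding semilandmarks

Semilandmarks sample curves, so their exact position along the curve is an
artefact of digitisation. `slide_semilandmarks()` relaxes them under the
Procrustes-distance criterion: for each non-anchor point the local tangent
is estimated by the central difference of its within-curve neighbours, and
the point moves along that tangent by the tangential component of its
deviation from the consensus — the orthogonal projection that minimises the
Procrustes distance. Curve endpoints are fixed anchors: sliding a free
endpoint under a one-sided tangent estimate is unconstrained, so endpoints
(and landmarks on no curve) never move.

Numerical safeguards:

* steps are clamped to 0.45 times the distance to the nearest curve
  neighbour, so points cannot cross along a curve in one pass;
* coincident neighbours (zero-length tangent) skip that point with a
  warning;
* after each sliding pass the sample is re-superimposed by GPA and the
  total Procrustes SS is compared to the previous pass; a pass that would
  increase it is reverted and iteration stops, so the outer objective is
  non-increasing. Five outer passes (default) are ample in practice; the
  loop stops early once the SS change drops below `tol` (1e-8).

Bending-energy sliding is deliberately out of scope: the distance
criterion is the one this analysis family specifies, and mixing criteria
would change what "minimised shape difference" means.

## Ordination

`tangent_pca()` treats the aligned coordinates as points in the linearised
shape space: the n × 3p matrix is column-centred and its covariance
eigen-decomposed, with no column scaling (coordinates share units).
`measurement_pca()` standardises each of the 12 linear measurements to
unit variance first (correlation PCA), because the measurements mix units
(mm, mm², mm³, turns, percentages). Both use sample (n − 1) denominators
and report at most min(n − 1, d) axes.

Axis signs are arbitrary in any PCA; for reproducibility each axis is
oriented so its largest-magnitude loading is positive. `axes_for_threshold()`
returns the smallest axis count whose cumulative variance proportion
reaches the threshold (default 0.95), taking the smaller count at exact
equality.

## Dispersion statistics

* `coefficient_of_variation()`: 100 · sd/mean with the sample sd; defined
  only for positive means, as is conventional for ratio-scale
  measurements. Where a dataset has repeated measurements per individual
  (left and right cochleae), `mean_by_individual_then_cv()` averages
  within individuals first so pseudo-replication does not deflate the CV.
* `disparity()`: either the sum of per-axis sample variances (the trace of
  the covariance matrix — invariant to rotation of the space, so disparity
  on a full PC-score matrix equals disparity on the centred coordinates)
  or the median Euclidean distance of specimens to their group centroid,
  a robust alternative. Disparity of a group is computed on the group's
  rows of the *joint* ordination, not on a group-specific re-ordination:
  the question is how much of the shared morphospace the group occupies.
  Point values are reported by default; a seeded percentile bootstrap
  (1000 reps) is available but off by default, since the quantities being
  mirrored are point estimates.

## Group tests

`procrustes_anova()` is a distance-based one-way linear model on the
superimposed coordinates: SST is the summed squared deviation from the
grand mean row, SSW from the group means, and the pseudo-F is
(SSB/(g−1))/(SSW/(n−g)). Significance comes from permuting group labels
across specimens — for a single-factor model, raw-row permutation and
residual randomisation coincide, so rows are permuted. The estimator
p = (1 + #{F* ≥ F}) / (1 + n_perm) includes the observed statistic, so
the smallest attainable p is 1/(n_perm + 1); the default 999 permutations
gives a floor of 0.001. Ties F* = F count as exceedances (conservative).
With `exact = TRUE` all distinct label arrangements are enumerated instead
and p = #{F* ≥ F}/N, which the tests compare against an independent
enumeration oracle.

`manova_pillai()` computes Pillai's trace V = Σ λᵢ/(1 + λᵢ) over the
eigenvalues of E⁻¹H and the standard F approximation. Pillai's trace is
the most robust of the classical MANOVA statistics to unequal group
dispersions — relevant here, where the single-species group is by design
less disperse than the many-species group. The precondition n − g > q is
enforced; callers reduce the axis count when it binds (the pipeline caps
the 95%-variance axis count at n − g − 1 automatically). At q = 1 the
statistic collapses algebraically onto the one-way ANOVA F, which the
tests assert to 1e-10.

`per_axis_anova()` tests each retained axis separately and Bonferroni-
adjusts over the number of axes tested. `covariate_test()` fits one
predictor at a time (categorical → group test; continuous → single-df
regression, distance-based or multivariate as the response dictates) and
adjusts over the predictor family — four, when side, sex, origin and log
skull length are each tested. Predictors are tested singly, not jointly:
with a deeply-sampled group of 18 the joint model would be badly
under-determined, and single-predictor tests match the sensitivity
analyses being reproduced.

## Sensitivity analyses

`subset_analysis()` is the heart of the robustness argument: for every k
in the requested range it re-runs the *entire* recipe — GPA, sliding,
PCA, axis re-selection, MANOVA — for every combination of k focal
specimens (non-focal specimens always retained), and reports the
distribution and median of the p-values. Sliding and axis selection are
repeated per subset rather than reused, because each subset changes the
consensus and the morphospace. Above `max_combos` (default 20000)
combinations per k, that many distinct subsets are drawn uniformly by
unranking random combination indices — exhaustive mode is available by
raising the cap. `restricted_comparison()` and `leave_one_out()` cover
the two other robustness designs: shrinking the comparator set (e.g.
congeners only) and removing a single influential specimen.

## The synthetic data generator

Real cochlear landmark data cannot be bundled, so `make_two_group_sample()`
generates data with the same statistical anatomy and known ground truth:

* the mean shape is a conical helix (`make_spiral_shape()`) parameterised
  by exactly the quantities a cochlea is measured by — turns, height,
  basal width, taper — sampled by offset curve copies (40 curves × 9
  points + apex = 361 landmarks in the `paper` preset; 4 × 5 = 20 in the
  `tiny` preset used by fast tests);
* focal specimens add isotropic Gaussian landmark noise (sd `within_sd`,
  default 0.01 in centroid-size units — a typical digitisation-plus-
  individual-variation scale) and optional tangential jitter emulating
  arbitrary semilandmark placement;
* each non-focal specimen is drawn around its own mean: the base shape
  plus `between_offset` times a smooth deformation field shared by the
  whole group (the group mean-shape offset) plus an equally-scaled field
  of its own (species scatter). Fields are spatially smoothed along
  curves and normalised to unit per-coordinate RMS, so `between_offset`
  is directly comparable to `within_sd`; the default 0.05 (five times the
  within-group noise) reproduces the strong among-species signal regime
  of the motivating design, with 18 focal and 51 other specimens;
* nuisance rotation, translation and scale are applied uniformly at
  random so superimposition is genuinely exercised;
* `make_measurement_table()` draws the nine raw measurements from a
  multivariate normal with specified means and CVs (defaults: plausible
  harbour-porpoise dimensions and representative intraspecific CVs) and
  an exchangeable correlation; the three ratio columns are recomputed
  from the raw draws, since a table whose derived columns contradicted
  their defining formulas would be invalid — their CVs are therefore
  emergent. Non-positive rows are redrawn (Gaussian rather than lognormal
  noise is adequate at CVs ≤ ~27%, where positivity violations are rare);
  a redraw rate above 10% errors.

Every generated object carries a `truth` attribute with the generating
parameters and seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: anatomical detail beyond the spiral scaffold,
allometry, left–right asymmetry, measurement error structured by observer
or instrument, and non-Gaussian tails. The tests establish that the
machinery is correct and calibrated, not that any particular biological
dataset satisfies its assumptions.

## Verification strategy and problem sizes

The test suite pins every computation to an independent route: Procrustes
solutions against brute-force rotation-grid and alternating-minimiser
oracles on planar data; permutation p-values against full enumeration of
label arrangements at n = 6; Pillai's trace against a long-hand H/E
evaluation and `stats::manova`; disparity identities against closed-form
hand calculations. Statistical behaviour is checked by seeded simulation
at deliberately desk-sized designs: type-I error of the permutation test
over 2000 null replicates (8 + 8 specimens, 20 landmarks, 199
permutations), power over 200 replicates at a 5-sigma offset (10 + 10),
and the subset-sensitivity sweep at 10 focal vs 20 other specimens with
every k from 2 to 9 enumerated exhaustively. The end-to-end pipeline runs
at the full study scale (18 + 51 specimens, 361 landmarks) on synthetic
data. These sizes were chosen as the smallest designs that make the
expected behaviour unambiguous.

## Known limitations

* Single-factor models only; no interactions, no phylogenetic correction.
* Sliding uses the Procrustes-distance criterion only (no bending
  energy), with tangents from curve neighbours; surfaces (as opposed to
  curves) are not supported.
* The Monte-Carlo subset fallback samples combinations uniformly, which
  for extreme k approaches exhaustive coverage anyway; no stratification
  is attempted.
* CVs are meaningful only for positive ratio-scale measurements; the
  package refuses non-positive means rather than guessing.
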