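---
title: "Principal Motif Values: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal Motif Values: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmvnet)
```

## The problem and the model

Structural brain networks in neurodegeneration are usually summarized by
node-centric graph measures, which largely ignore how individual edges
combine into local building blocks.  `pmvnet` implements a motif-based
alternative built on the *regional radiomics similarity network* (R2SN): a
per-subject, region-by-region network whose edge weights are Pearson
correlations between regional radiomic feature profiles extracted from
structural MRI.  Because the R2SN is a full similarity matrix, every triple
of regions forms a triangle; the informative structure is not which edges
exist but what *kind* of edges they are.

Each edge is dichotomized twice, at cohort medians:

* **strength** — the R2SN weight, STRONG if strictly above the median of
  the pooled upper-triangle edge weights of all subjects, otherwise WEAK;
* **length** — the Euclidean distance between region centroids (mm), LONG
  if strictly above the median of the `choose(N, 2)` pair distances,
  otherwise SHORT.

This yields four edge classes.  A triangle's identity is the *multiset* of
its three edge classes — orderings that differ by rotation or reflection
are the same motif — so there are exactly `choose(4 + 3 - 1, 3) = 20`
triangle types.  The census counts, for every region, how many of the
`choose(N - 1, 2)` triangles through it fall into each type, giving a
20 × N count matrix per subject with two conservation identities: each
region's column sums to `choose(N - 1, 2)` and the grand total is
`3 * choose(N, 3)`.

The **Principal Motif Value** (PMV) compresses this census to one number
per region.  Each motif-type row is standardized to zero mean and unit
variance across regions (population-SD convention), all subjects'
standardized matrices are pooled along the region axis, the 20 × 20
covariance matrix (sample, `1/(n-1)` convention) is eigendecomposed, and
the loading `v` is the leading eigenvector.  A subject's PMV map is
`PMV[j] = sum_t Z[t, j] v[t]`.  Positive PMV indicates a region whose
triangles are dominated by weaker, shorter connections.

Downstream inference is deliberately nonparametric: Shapiro–Wilk screening
motivates Kruskal–Wallis maps across diagnostic groups with Bonferroni
control over regions, post hoc Mann–Whitney comparisons expressed as
Z maps through the closed form

$$Z = \frac{U - n_1 n_2 / 2}{\sqrt{n_1 n_2 (n_1 + n_2 + 1)/12}},$$

Pearson correlation maps against clinical scores, Stouffer weighted-Z
meta-analysis across sites, and spatial association of a Z map with
region × gene (or receptor) tables via one-component PLS with permutation
significance and bootstrap gene Z-scores.

## Orientation of the PCA

The source description of the PCA step is internally inconsistent: a
literal reading standardizes per region and builds an N × N covariance,
but then the projection would be 20-dimensional, contradicting both the
stated per-region output and the interpretation of per-motif contribution
percentages.  `pmvnet` therefore treats **motifs as variables and regions
as observations** (a 20 × 20 covariance, per-region scores), which
satisfies both; the literal orientation remains available through
`fit_pmv_model(..., orientation = "regions")` for comparison.

Two further identifiability choices:

* **Cohort-common loading.**  One loading vector is fitted on a reference
  cohort and applied to every subject.  Per-subject PCA would leave
  per-subject sign and rotation ambiguity and break group comparison.  The
  reference defaults to all subjects (`pmv_reference = "all"`) and can be
  restricted, e.g. to controls.
* **Sign anchor.**  Eigenvectors are defined up to sign, so the loading of
  the all-WEAK_SHORT motif type (catalog type 20) is forced nonnegative.
  This makes repeated fits bit-identical and pins the interpretation of
  positive PMV to weak/short-dominated regions.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `target_count` | 25 | features retained by greedy correlation-based selection |
| `r_cap` | 0.90 | maximum tolerated absolute pairwise feature correlation |
| `alpha` | 0.05 | family-wise level of every Bonferroni correction |
| `n_perm` | 999 | permutations for spatial significance |
| `n_boot` | 1000 | bootstrap replicates for gene Z-scores |
| `top_k` | 500 | exported top genes (capped at the gene count) |
| `noise_sd` | 0.1 | subject-level feature noise in the generator (archetype scale ≈ 1) |

Feature selection is specified only loosely in the source method
("correlation-based, retaining 25"); the concrete rule here is greedy
elimination: while any surviving pair exceeds `r_cap` *or* more than
`target_count` features remain, drop the feature with the highest mean
absolute correlation to the surviving rest, breaking ties by keeping the
lower original index.  The rule is deterministic; note that the cap clause
can legitimately push the survivor count below `target_count` when the
survivors are still too collinear.

Other numerical conventions worth knowing:

* **Ties at the medians** go to the WEAK / SHORT side (a strict `>`
  defines STRONG/LONG); the source is silent and continuous weights make
  ties measure-zero anyway.
* **Negative R2SN weights** are classified by the same threshold rule, with
  no absolute value taken.
* **Z denominators** carry no tie correction, exactly as the closed form
  prints; `tie_correction = TRUE` switches to the tie-corrected variance.
* **Degenerate inputs are errors, not imputations**: constant feature
  columns fail min-max normalization by name; zero-variance regional
  profiles fail R2SN construction by name; constant count rows standardize
  to zeros; Shapiro–Wilk on constant cells reports `NA` rather than
  crashing.
* **Permutation p-values** use the `(1 + exceed) / (1 + n_perm)` estimator,
  which is conservative (valid) under exchangeable nulls.

## The spin-test question

Spatially constrained permutation nulls (spin tests) require spherical
cortical coordinates that a synthetic ellipsoid atlas does not have.  The
spatial-association functions therefore accept *precomputed* permutation
index matrices from any external spin or variogram tool and fall back to
uniform permutation otherwise; the mode used is recorded in the result
(`permutation_scheme`).  With supplied permutations equal to uniform draws
the two modes agree exactly.

## What the synthetic generator emulates — and what it does not

`generate_atlas()` samples centroids uniformly in a bounded ellipsoid
(semi-axes 70 × 85 × 60 mm) and labels the innermost 15% radial shell
"subcortex" (functional partition unassigned there), the next 10%
"limbic", and remaining cortex by direction into four lobes and seven
angular functional sectors.  This supports partition summaries without
claiming any real anatomy.

`generate_cohort()` builds regional archetype profiles from three scaled
coordinate gradients plus a radial gradient and region-specific offsets,
so R2SN matrices acquire realistic block structure and non-degenerate
motif distributions; each subject adds Gaussian noise (`noise_sd = 0.1`
against archetype scale ≈ 1).  Group effects are injected *upstream* of
network construction, on the feature profiles of target regions, so a
planted effect exercises the entire pipeline:

* `strength-shift` blends a target region's profile towards the cohort
  mean profile with weight `min(effect_size, 1)`, raising that region's
  edge strengths;
* `profile-decorrelation` adds a fixed random direction scaled by
  `effect_size`, lowering its correlations everywhere.

The source reports no quantitative effect sizes for its group
differences, so synthetic magnitudes are calibration choices, not
reproductions.  The default planted condition used throughout the
validation suite (`effect_size = 0.8`, strength-shift, affecting MCI and
AD) was chosen as the smallest round blending weight at which a
5-of-60-region effect is reliably localized at 30 subjects per group, and
then frozen.  Clinical scores follow
`baseline + slope × dose + noise` with dose 0 in controls; spatial maps
use the mixture `rho·z(target) + sqrt(1 - rho²)·z(noise)` so their
expected correlation with a target map is exact.

What passing tests on this generator do **not** show: robustness to real
radiomic feature distributions (heavy tails, site effects), to spatial
autocorrelation structure of real cortex (hence the pluggable spin nulls),
to registration or segmentation error, or to the demographic confounding
of real cohorts.  The generator makes no attempt to match real
demographic distributions, and the dataset-level numbers reported for the
original multisite study (pooled medians 0.75/76.11, cross-dataset Z-map
correlations 0.78/0.55/0.54, PLS r = 0.35 with 12.2% variance, motif
contributions 43/14/12%) depend on those real data and are context, not
reproduction targets.

## Validation design and problem sizes

The test suite validates every stage against an independent route:

* the census against a naive triple-loop enumerator (50 random labelled
  networks, N ∈ 5..15) plus the conservation identities and
  label-permutation equivariance — the production algorithm itself is
  algebraic (per-class indicator matrix products), so the two routes share
  no code;
* R2SN weights against a from-the-definition Pearson oracle, and the PLS1
  weights against an independent PLS implementation;
* eigenvalues against characteristic-polynomial roots on a 4-type
  reduction;
* the Mann–Whitney closed forms against exhaustive enumeration of all
  rank assignments for `n1 + n2 <= 8` and grid checks up to 30 per group;
* family-wise error on 200 null cohorts (3 × 30 subjects, 60 regions) and
  power on 50 planted replicates of the calibrated condition;
* permutation validity of the PLS p-value on 200 null replicates
  (`n_perm = 199`).

One construction deserves a note: the "planted gene among 199 noise
genes" recovery check residualizes the noise maps against the target.
With i.i.d. noise columns each chance correlation is O(1/sqrt(N)) and the
one-component score aggregates them, which caps the achievable
score–target correlation near 0.93 at these sizes for *any*
implementation; orthogonal noise isolates the property actually under
test (that the component locks onto a planted signal).

These sizes (60-region atlases, 20–30 subjects per group) were chosen as
the smallest cohorts at which the motif census and the rank statistics are
well away from their small-sample regimes; `scripts/acceptance.R`
recomputes the same quantities end-to-end at the same scales.

## Known limitations

* Single-modality networks: the PMV summarizes one similarity network and
  cannot exploit multimodal information.
* The motif catalog order is a package convention (lexicographic under
  STRONG_LONG < STRONG_SHORT < WEAK_LONG < WEAK_SHORT); published figures
  that index motifs 1–20 under an unavailable ordering cannot be mapped
  onto it with certainty, so cross-references to "motif 13/14/19" style
  labels are not claimed.
* Whether strength medians should be pooled once or per dataset in
  multi-dataset work is an open choice; `compute_thresholds()` is
  explicit about its provenance so either policy can be implemented by
  the caller.
* The PLS variance-explained share is reported for the predictor block;
  the corresponding published number is ambiguous about its denominator.
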