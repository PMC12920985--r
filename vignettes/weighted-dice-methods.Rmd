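---
title: "Distance-aware Dice coefficients: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-aware Dice coefficients: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WeightedDice)
```

## The model

A binary segmentation mask is a 2-D or 3-D boolean grid; `X` and `Y`
denote the positive-element sets of a reference and a predicted mask of
one shape. The classical Dice coefficient `2|X∩Y|/(|X|+|Y|)` counts
misplaced elements but ignores where they are. Both coefficients here
reintroduce location through *nested dilation environments*: `X₀ = X`,
and `Xᵢ` is `Xᵢ₋₁` dilated once by a fixed structuring element. An
element of ring `Xᵢ∖Xᵢ₋₁` lies exactly `i` dilation steps from the
mask.

The **weighted Dice coefficient** assigns weight 1 to the mask, `νᵢ` to
ring `i`, and 0 beyond `Xₙ`, with `1 > ν₁ > … > νₙ > 0` strictly; the
coefficient is the generalised Dice ratio of these weight maps. The
strict ordering is not cosmetic: the proof that the ratio stays in
`[0, 1]` — the element-wise minimum map has a sum no larger than either
weight-map sum, hence `2s ≤ s_X + s_Y` — relies on it, so the
configuration validator rejects non-decreasing weights rather than
silently reordering them. The two algebraically equivalent forms (the
set expression and the fast min-map expression) are both implemented;
their agreement to 1e-12 over seeded random 2-D and 3-D suites is a
standing regression test, since any divergence can only be a bug.

The **loss-based Dice coefficient** keeps the overlap numerator but adds
`|X∖Y*| + |Y∖X*|` to the denominator, where `X*`, `Y*` are the
environments at a configurable index (default: the outermost). Since the
denominator can only grow, `LDC ≤ DSC` identically — a property the test
suite asserts on every random pair. The **hybrid WDC** zeroes the WDC
whenever `DSC = 0`; it exists because the WDC awards a residual to
predictions whose environments merely brush the reference, which is
undesirable when ranking fully-wrong masks.

## Parameters and defaults

* `nEnv = 3` environments with weights `ν = (0.7, 0.5, 0.3)`. These
  divide the unit interval simply and symmetrically; the depth of three
  steps matches how far expert annotators of fuzzy-boundary modalities
  plausibly disagree. Weights are in coefficient units (dimensionless),
  one per dilation step.
* `connectivity = "edge"`: one dilation step adds elements sharing an
  edge (2-D) or a face (3-D), i.e. one unit of L1 distance; `"full"`
  (8- / 26-neighbourhood, Chebyshev distance) is available but never the
  default, because the cross-shaped element keeps "k steps away" equal
  to "L1 distance k".
* `ldcEnvIndex = nEnv` by default but independently configurable.
* WDC values are comparable only between runs with identical
  parameters and comparable image resolution: the same physical
  disagreement spans more pixels at a finer grid, so cross-dataset use
  requires deliberate parameter choice.

### Numerical and boundary conventions

* Dilation is clipped at the grid border; an environment never extends
  outside the array. A segment near the field-of-view edge therefore has
  a smaller weight-map sum than the same segment mid-grid. This matches
  standard binary-morphology behaviour.
* Degenerate pairs: both masks empty gives every metric 1.0, exactly one
  empty gives 0.0; both cases carry an explicit flag so downstream
  statistics can exclude them deliberately. The value 1.0 for the
  both-empty case treats "no segment, none predicted" as perfect
  agreement; the flag exists precisely because other conventions are
  defensible.
* Weight sums accumulate in double precision; identity-type assertions
  in the tests use an absolute tolerance of 1e-12.
* 3-D dilation treats voxels as isotropic. NIfTI voxel-spacing metadata
  is read and reported, and anisotropic spacing triggers a warning, but
  spacing never alters the metrics — a deliberate simplification that
  users of strongly anisotropic volumes should weigh.

## Mask preprocessing

`resizeMask()` reproduces the usual annotation-to-network-grid
conversion: the mask is interpolated as a real-valued field and
binarised at a coverage threshold, 0.25 by default. The interpolation is
the exact block mean for integer downscale factors — which makes the
threshold a literal fractional-coverage rule — and bilinear otherwise.
The comparison is strictly greater-than; the choice is arbitrary but
fixed, and the tests probe it on both sides of the boundary.
`minPositiveFilter()` implements the companion inclusion rule (drop
slices with fewer than 6 positive pixels), and `stackSlices()` /
`sliceMask()` convert between per-slice 2-D masks and 3-D volumes with
the slice index on axis 1.

## The synthetic validation design

Validating a quality metric requires masks of *known* visual quality.
With no patient data in the package, the synthetic module generates
both sides: seeded phantoms (unions of random filled ellipses or
ellipsoids — adequate because the coefficients depend only on set
geometry, not on intensity or anatomy) and degradations targeting a
five-class ordinal rubric:

| class | construction |
|---|---|
| 4 excellent | sparse one-step boundary flips (add probability 0.15, drop 0.09), anchors of added pixels protected so no fully-FP fragment forms |
| 3 good | two-step dilation on a random half-space, one-step erosion on the rest: outlines clearly cross, some errors beyond one step |
| 2 decent | uniform two-step dilation or erosion (nested outlines), or one substantial distant fully-FP component |
| 1 poor | translation until the overlap is ≥ 1 element but under half the smaller mask |
| 0 fully wrong | relocation with a gap over twice the environment depth (WDC exactly 0), or an empty prediction; the empty form is the fallback when a grid-spanning phantom leaves no room |

`rubricScore()` grades any pair against the same semantics with explicit
constants: majority overlap at 0.5 of the smaller mask, fully-FP/FN
components labelled under the metric connectivity, "nested" meaning
containment with margin beyond one step, "near-perfect" meaning every
error within one step of the other mask. These thresholds
operationalise qualitative wording; they are documented constants, not
claims about how human raters decide. Degradations grade back into
their intended class on ≥ 97% of seeded suites (the test requires
≥ 90%; residual misses are geometric edge cases such as thin components
severed by erosion).

What the phantoms deliberately omit: PET intensity, partial-volume
blur, scanner noise, anatomy-shaped segments, and learned-model error
structure. Passing validation therefore shows the metrics *order and
separate constructed quality classes* as intended — it does not certify
correlation magnitudes on clinical data, which depend on the real error
distribution.

The default experiment uses 200 pairs on 48×48 grids (40 per class,
two-blob phantoms with semi-axes 2–5): large enough for stable rank
correlations and class standard deviations, small enough that the full
experiment runs in seconds on one core. Under it, Spearman ρ with the
scores is consistently higher for WDC than for DSC (≈ 0.94 vs ≈ 0.93
across seeds), and the within-class sd of WDC is roughly 40–60% of the
DSC's in classes 3 and 4 — the qualitative pattern that motivates the
weighted coefficient. The absolute correlations exceed what mixed
clinical data shows, because constructed degradations are cleaner than
CNN failure modes.

## Statistics

`spearmanCorrelation()` computes tie-corrected Spearman ρ (average
ranks, then product-moment correlation) with a two-sided p-value from
the t approximation on n − 2 degrees of freedom — appropriate at the
suite sizes used here, where exact permutation is infeasible; an exact
permutation option covers n ≤ 8. `fTestVariances()` is the two-sided
variance-ratio F test (p = 2·min(P(F≤f), P(F≥f)), capped at 1) and
refuses pairs where both samples are constant, which is why a score
class where two metrics are identically zero is skipped rather than
tested. FDR control is Benjamini–Hochberg step-up. Standard deviations
use the n − 1 denominator throughout; single-member classes report an
undefined sd rather than zero.

## Known limitations

* Metrics assume hard binary masks; probabilistic outputs must be
  thresholded upstream, and the readers enforce this rather than
  guessing a cutoff.
* Isotropy: one dilation step is one element along any axis, regardless
  of physical voxel size.
* WDC values are parameter-bound; there is no calibration mapping a WDC
  under one (n, ν) choice onto another.
* The rubric scorer is a fixed operationalisation of qualitative
  criteria; near class boundaries its grade can legitimately differ
  from a human's.
* Environment clipping at borders slightly deflates weight sums for
  segments touching the field-of-view edge, which marginally raises WDC
  there relative to an unbounded grid.
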