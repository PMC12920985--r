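# WeightedDice

Distance-aware Dice coefficients for evaluating 2-D and 3-D binary
segmentation masks.

## The problem

The Sørensen–Dice similarity coefficient,

```
DSC = 2|X ∩ Y| / (|X| + |Y|)  ∈ [0, 1],
```

is the standard agreement measure between a reference segment *X* and a
predicted segment *Y*, but it depends only on *how many* elements are
misplaced, never on *where* they are. Two predictions with identical
overlap counts score identically even if one errs by a single pixel at
the boundary and the other places a whole component far from the target.
For modalities with intrinsically fuzzy object boundaries — PET tumour
delineation being the canonical case, where the partial-volume effect
makes even expert annotators disagree by a few voxels — this makes the
DSC a poor proxy for how a human would grade a mask.

This package implements two modifications that fold location into a
single overlap score, for anyone evaluating medical-image segmentation
(or any binary segmentation where near-misses should count):

**Weighted Dice coefficient (WDC).** Surround each mask with *n* nested
environments `X = X₀ ⊆ X₁ ⊆ … ⊆ Xₙ`, each obtained by one binary
dilation step (edge-sharing 4-neighbourhood in 2-D, face-sharing
6-neighbourhood in 3-D, by default), and give ring `Xᵢ \ Xᵢ₋₁` a weight
νᵢ with `1 > ν₁ > … > νₙ > 0`:

```
WDC = 2 (|X∩Y| + Σᵢ νᵢ|Xᵢ∩Yᵢ \ (Xᵢ₋₁∩Yᵢ₋₁)|)
      ─────────────────────────────────────────────
      |X| + Σᵢ νᵢ|Xᵢ\Xᵢ₋₁| + |Y| + Σᵢ νᵢ|Yᵢ\Yᵢ₋₁|
```

Equivalently (and how the package computes it): build each mask's weight
map (1 on the mask, νᵢ on ring *i*, 0 outside), sum them to get `s_X`
and `s_Y`, sum the element-wise minimum of the two maps to get `s`; then
`WDC = 2s / (s_X + s_Y)`. Both formulations are implemented and verified
against each other. Defaults: `n = 3`, weights `0.7, 0.5, 0.3`.

**Loss-based Dice coefficient (LDC).** Keep the DSC numerator but
penalise elements that fall outside the *other* mask's dilated
environment `X* = X₃`, `Y* = Y₃`:

```
LDC = 2|X ∩ Y| / (|X| + |Y| + |X \ Y*| + |Y \ X*|)  ≤  DSC.
```

A **hybrid WDC** (WDC forced to 0 whenever DSC = 0) removes the small
positive credit WDC can give a completely misplaced prediction.

Because no patient data ships with the package, a seeded synthetic
module generates phantom masks and degrades them into five ordinal
quality classes (0 fully wrong … 4 excellent), with a programmatic
scoring rubric, so the metrics' agreement with visual quality grades can
be validated end to end — Spearman rank correlation with the scores,
per-class spread, and pairwise F-tests of variance equality with
Benjamini–Hochberg FDR control.

## Worked example

A 3×3 reference square, one prediction shifted one row (six misplaced
pixels at the boundary), one prediction of the same size far away:

```r
library(WeightedDice)
x     <- array(0, c(10, 10)); x[2:4, 2:4]     <- 1
yNear <- array(0, c(10, 10)); yNear[3:5, 2:4] <- 1
yFar  <- array(0, c(10, 10)); yFar[7:9, 7:9]  <- 1
round(rbind(near = allMetrics(x, yNear), far = allMetrics(x, yFar)), 3)
#>        DSC   WDC   LDC hybridWDC
#> near 0.667 0.843 0.667     0.843
#> far  0.000 0.047 0.000     0.000
```

The DSC rates the boundary-shifted prediction 0.667 with no credit
beyond the overlap; the WDC lifts it to 0.843 because every misplaced
pixel sits one dilation step from the other mask. The distant prediction
keeps DSC = 0; its environments barely brush the reference's, so WDC
gives a residual 0.047 — exactly the behaviour the hybrid variant
removes (0.000).

The synthetic validation experiment in one call:

```r
ex <- runValidationExperiment(nPairs = 50, shape = c(48, 48), seed = 1)
round(sapply(ex$spearman, testStatistic), 3)
#>       DSC       WDC       LDC hybridWDC
#>     0.916     0.933     0.920     0.933
subset(ex$classSummaries, metric %in% c("DSC", "WDC") & score >= 3)
#>    score metric  n       min      mean       max         sd
#> 13     3    DSC 10 0.5891473 0.6584514 0.7099567 0.03375501
#> 14     3    WDC 10 0.7380304 0.7678047 0.8039978 0.02008639
#> 17     4    DSC 10 0.8842105 0.9180150 0.9545455 0.02023764
#> 18     4    WDC 10 0.9159817 0.9431184 0.9624060 0.01528828
```

The weighted coefficient correlates with the ordinal quality scores at
least as strongly as the DSC and spreads visibly less within the good
and excellent classes — the pattern that motivates preferring it when
grading near-correct masks.

## Command line

```sh
Rscript inst/cli/dicemetrics.R eval --reference ref.png --prediction pred.png
Rscript inst/cli/dicemetrics.R batch --manifest pairs.csv --out results.csv
Rscript inst/cli/dicemetrics.R simulate --n-pairs 200 --seed 1 --out report/
Rscript inst/cli/dicemetrics.R fixtures --out fixtures/ --n-pairs 10 --seed 1
```

Masks are read from PNG/TIFF (2-D) or NIfTI (3-D); any nonzero value is
positive. Batch manifests are CSVs with columns `id`, `reference`,
`prediction`, and optionally `score` (0–4), which triggers the
statistical battery. Metric options: `--n-env`, `--weights 0.7,0.5,0.3`,
`--connectivity edge|full`, `--ldc-env`. Coordinates follow array-index
convention, axis order (slice, row, column) for 3-D.

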