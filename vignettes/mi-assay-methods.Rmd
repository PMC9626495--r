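---
title: "Methods: the morphometric imaging aggregation biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the morphometric imaging aggregation biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The assay and its statistic

Skin fibroblasts plated on a 3-D extracellular matrix aggregate over 48
hours. In Alzheimer's disease (AD) lines the cells migrate more slowly and
coalesce into a small number of large aggregates; non-AD-dementia and
healthy-control lines form many small ones. The morphometric imaging (MI)
assay turns this phenotype into a single number per patient sample: in each
qualified 10x field image at 48 h, the aggregate areas are measured
(pixel^2), their mean is `A`, their count is `N`, and the image score is
`ln(A/N)`. Image scores are averaged (unweighted) over the qualified images
of a well, and the well means are averaged (unweighted) once more over the
eligible wells of the plate. The plate value — written `Ln(A/N)` — is the
biomarker; alongside it the package reports the sample standard deviation
over all contributing image scores, the plate's technical-replicate spread.
Unweighted means at both levels are a deliberate reading of the averaging
hierarchy: wells that contributed fewer qualified images are not
down-weighted, so one noisy well cannot silently dominate.

`ln(A/N)` is dimensionless but pixel-scale-bound: multiplying every area by
`k` shifts every image, well, and plate score by exactly `ln(k)` (this is a
property test in the suite). Scores are therefore only comparable at a fixed
acquisition geometry, which is why the synthetic frame is pinned at
1000 x 1000 8-bit pixels and why no attempt is made to express areas in
micrometres — the source imagery's pixel calibration is not part of the
computational contract.

## The image chain

Both the attachment-phase cell count and the 48-h aggregate measurement use
one filter chain, applied in this order:

1. **Despeckle, three passes** — 3x3 median filter, edge-replicated borders.
   Removes Poisson shot noise without moving object boundaries.
2. **Minimum filter radius 0.5, three passes** — grayscale erosion over the
   5-pixel cross (centre + 4 edge neighbours). Shaves faint halos and splits
   thin bridges between touching objects; it erodes each object boundary by
   roughly 3 px in total, which is accounted for in the synthetic-object
   sizing below.
3. **Rolling-ball background subtraction, radius 20 px** — the background is
   the grey opening of the image with an elliptic paraboloid osculating the
   radius-20 ball at its bottom (the classical paraboloid approximation of
   the rolling ball). The quadratic structuring function is separable, so
   the opening is four O(n) envelope passes (erode rows/columns, dilate
   rows/columns) rather than a 41x41 neighbourhood sweep. No pre-smoothing
   is applied. The result is clipped at 0.
4. **Binarisation** — iterative intermeans (IsoData/Ridler–Calvard) on a
   256-bin histogram: the threshold converges to the midpoint of the two
   class means; foreground is strictly above it. A constant image yields an
   empty mask, not an error. Because an automatic threshold always splits
   something — on a noise-only field it would carve the upper noise tail
   into spurious "particles" — the mask is declared empty unless the class
   means separate by at least 2.5 times the summed within-class standard
   deviations (populated fields sit at 4–5 on this ratio, noise-only fields
   near 1.5).
5. **Particle analysis** — 8-connected components with pixel area at or
   above 180 px^2 (inclusive bound). The same 180 px^2 floor is used at 48 h:
   no separate aggregate floor is defined by the assay, and a single
   consistent default is preferable to an undocumented second knob
   (`mi_defaults()$particles$min_aggregate_area` overrides it).

Counting returns the particle count; aggregate measurement returns
`(A, N) = (mean area, count)` and flags the image unusable when `N = 0`
(the score is undefined there; the QC layer simply drops such images).

Each filter is validated against an independent brute-force implementation
(sliding-window median/minimum by direct enumeration, flood-fill labelling)
on small random images; the rolling-ball step is validated against its
defining properties — exact removal of flat and affine backgrounds away
from the frame border, preservation of compact bright features. Note the
paraboloid background transform is exact for an affine ramp only in the
interior: within about `s·r` pixels of the border (slope `s`, radius `r`)
the envelope is boundary-limited, so the property is asserted at
field-realistic gradients, where the residual is far below 5% of the
gradient amplitude.

## QC gates

Plating targets 417 cells per 10x field (`ln 417 = 6.033`; and
`round(exp(6.033)) = 417` is itself asserted in the tests). A field passes
when `ln(count)` lies in the inclusive window `[5.811, 6.214]`. The window
is asymmetric around 6.033 and is taken verbatim as the authoritative gate;
the frequently quoted 330–500 cell translation is only approximate (334 is
the lowest passing count, and 500 itself falls marginally outside — both
asserted in the tests). A well passes with at least 5 of 9 passing fields;
a plate continues with at least 3 of 4 passing wells, otherwise it is
flagged `repeat_required`. Nine QC fields per well is the default; the well
gate accepts `n_fields = 10` by configuration, since acquisition protocols
vary in whether a tenth field is taken. The gates are monotone (adding a
passing field or well can never flip a verdict from pass to fail), which is
property-tested. Culture-level rules (post-thaw viability, 14-day growth
limit, passage <= 15) are wet-lab constraints with no imaging analogue;
they survive only as metadata columns on the cohort tables.

## Cutoff and diagnostics

The diagnostic cutoff is the 95th percentile of the 27 healthy-control
(AHC) plate values, computed with the exclusive rank convention: on the
ascending order statistics the interpolation rank is `r = p(n+1)` (here
`0.95 x 28 = 26.6`), and the cutoff interpolates linearly between the 26th
and 27th values: `6.75 + 0.6 x (7.13 - 6.75) = 6.978`, reported as 6.98.
Among percentile conventions this is `stats::quantile(type = 6)`, and it is
the one that reproduces the published 6.98 from the published control
values — the deciding criterion, since prose descriptions of percentile
interpolation are notoriously ambiguous. The convention is held fixed, and
`percentile_cutoff()` is cross-checked against the type-6 estimator on
random reference sets.

Classification calls AD when the plate score is **strictly above** the
cutoff. The biology fixes this direction — fewer, larger aggregates mean a
higher mean area per aggregate — and so do the cohorts themselves: every
validated AD value (minimum 7.10) exceeds 6.98 and every validated
non-AD-dementia value (maximum 6.77) is below it. A published account of
the assay contains one sentence stating the opposite direction; it is
inconsistent with the accompanying values and figures and is treated as an
erratum rather than silently ignored. A score exactly at the cutoff is
called non-AD: the cutoff is the upper bound of the normal reference
interval, so a value at the bound is still within normal limits.

Accuracy is reported against gold-standard (autopsy/genetic) labels with the
AD class positive: confusion counts, then sensitivity, specificity, PPV,
NPV, and accuracy, each with an exact (Clopper–Pearson) 95% binomial
interval via `stats::binom.test`; a brute-force tail-inversion oracle
confirms the intervals to 6 decimals over all `n <= 50` in the tests. The
healthy controls that defined the cutoff are unequivocal by definition and
never enter the accuracy tables — passing them to `confusion_report()` is
an error, not a silent drop. Group score distributions are summarised by
Gaussian fits (sample mean/sd, the MLE), with a buffer boundary four
standard deviations from each group mean toward the inter-group gap;
"density-adaptive" histogram binning for plots is concretised as
equal-count (quantile) bins with `ceiling(sqrt(n))` bins, a plotting-only
choice with no downstream effect.

## The synthetic data generator

No raw micrographs are published for this assay, so the package ships a
generator that emulates the two endpoint morphologies with known ground
truth, making every stage testable end to end.

Objects are discs with normally distributed radii (truncated at 2 sd),
blurred by a Gaussian point spread (sigma 1.5 px), on a background of 30
(foreground 150) carrying an additive illumination plane (peak-to-peak 12
grey levels), Poisson shot noise, and Gaussian read noise (sd 6), rounded
into the 8-bit range. Regime defaults:

| regime | objects | radius (px) | placement |
|---|---|---|---|
| attachment | 417 | 13 ± 1 | jittered grid, non-overlapping |
| aggregated, AD-like | 5 | 48 ± 3 | uniform, merging allowed |
| aggregated, non-AD-like | 60 | 13 ± 1 | uniform, merging allowed |

The attachment radius is sized so that after the chain's ~3 px erosion a
cell still clears the 180 px^2 particle floor with margin (radius 13 px ->
roughly 314 px^2 detected), and placement uses a jittered grid — a
deterministic construction that guarantees a 2 px edge-to-edge gap and
fails with an informative error naming the limiting parameter when the
geometry cannot host the requested count, instead of stalling in rejection
sampling. Ground truth for the aggregated regimes is the set of 8-connected
components of the union of discs — what merged, not what was placed. The
aggregate sizes are calibrated by construction, not by fitting: five
radius-48 discs give a measured `ln(A/N)` near 7.2–7.5 (above the 6.98
cutoff with margin even after erosion), sixty radius-13 discs give roughly
1.9 (far below 6.5), so a full synthetic plate straddles the cutoff by
regime. The simulated per-field plating count is drawn as `N(417, 25)` —
a realistic pipetting spread under which fields essentially always pass QC,
as they should for intact cultures.

Reproducibility contract: one root seed; every field and every cohort group
draws from a sub-stream derived by stable integer mixing of the seed with
its labels (`derive_seed()`), so results are independent of generation
order, and identical spec + seed is bit-identical.

The cohort generator draws per-group plate values from Gaussians whose
default means and standard deviations are the sample statistics of the
packaged cohort tables. What the synthetic data does **not** emulate:
filopodial network formation and its dissociation over the 2–24 h time
course (only endpoint morphologies are rendered), irregular aggregate
shapes, focus errors, and between-plate batch effects. Passing tests
therefore demonstrate that the computational chain is correct and
well-calibrated on its stated object model — not that the wet assay
achieves the published accuracy on new patients.

## Numerical choices and problem sizes

Degenerate inputs are policy, not errors, wherever the assay has a natural
downstream handler: constant images binarise to empty masks, `N = 0` images
are flagged unusable, empty wells are ineligible, and a plate with fewer
than 3 eligible wells raises a typed rejection (`mi_plate_rejected`)
mirroring the repeat-assay rule. Fixture CSVs are md5-verified at load.
Percentile ranks outside `[1, n]` raise an insufficient-reference error
rather than extrapolating.

The test suite runs the counting-accuracy property on 50 full-size
(1000 x 1000) fields spanning 300–550 objects — the published validation
claim is a relative error below 7%, and the generator/chain pair achieves
exact recovery on nearly all fields — plus one full synthetic plate per
regime and 1000 replicate cohorts for generator parameter recovery. These
sizes keep the whole suite within a few minutes on a single core while
exercising every stage at canonical geometry.

## Known limitations

- Absolute areas are uncalibrated (pixel^2, not µm^2); scores are tied to
  the canonical geometry by the `ln(k)` covariance above.
- The rolling-ball variant is the paraboloid approximation; a true
  sphere-rolling implementation differs slightly near features comparable
  to the ball radius. The variant is documented and held fixed.
- Whether the 48-h measurement used the same plug-in parameters as the
  counting step is not specified by the assay description; this package
  uses one chain for both, with the aggregate floor exposed as a config
  override.
- The synthetic phenotype gap is wider than the clinical one (simulated
  plates score ~7.4 vs ~1.9, whereas the cohorts span 4.2–10.7 around the
  6.98 cutoff); the generator demonstrates pipeline correctness, not
  clinical difficulty.
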