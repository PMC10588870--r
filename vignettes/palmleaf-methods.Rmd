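---
title: "Methods: hybrid leaf-area estimation for palmate leaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid leaf-area estimation for palmate leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmleaf)
```

## The estimation problem

Total leaf area per plant is a standard proxy for growth and
photosynthetic capacity, but measuring every leaf of a cassava plant
(often 100–400 leaves) is prohibitively slow.  The package implements a
stratified-sampling estimator built on three observations:

* per-leaf area `LA` is accurately measurable from a calibrated
  white-background photograph;
* leaves of similar (L, W) footprint have similar area, so a plant's
  leaves can be binned on a physical *scoring board* (nested squares,
  3.5–15.5 inch in 1-inch steps) and each bin summarized by a few
  randomly sampled representatives;
* for palmate leaves `LA` is almost proportional to the rectangle
  `L × W`, so a one-parameter allometric model `LA = a·L·W` can replace
  photography entirely once `a` is known.

The plant total is the cluster sum `Σᵢ (LA_rep · LN)ᵢ`.  With every
leaf its own representative this telescopes to the exact per-leaf sum
(the identity limit, tested to machine precision); with `k`
representatives per cluster it is an unbiased stratified estimator whose
error is within-cluster sampling noise.

## Image measurement

`segment_leaf()` assumes the field protocol: one leaf per image, darker
than a predominantly bright background, with a known scale (`ppcm`,
pixels per centimeter, supplied directly or calibrated from a square
fiducial by `calibrate_scale()`).  Luminance is thresholded by Otsu's
method (a fixed threshold can be forced), interior holes are filled
(insect damage, specular spots), components are labelled with
8-connectivity, components touching a border margin (default 2% of the
image side — rulers, board edges, fiducials) are discarded, and the
largest remaining component is the silhouette.  Area is the foreground
pixel count divided by `ppcm²`.

Two descriptor algorithms are offered because the manual convention —
`L` from the central-lobe apex to the "southernmost" lobe apex, `W`
between the farthest-protruding lateral apices — involves human choices
no algorithm reproduces exactly:

* **axis-extent** (default): silhouette extents along and across the
  principal axis of the second-moment ellipse.  Deterministic, exact for
  convex shapes (rectangle tests pass within one pixel, rotation
  invariance within 2%), but blind to lobe structure.
* **tip-based**: lobe apices are local maxima of the contour's radial
  distance from the centroid.  A candidate apex must exceed the higher
  of its two flanking sinus minima by 15% of the maximal radial distance
  (`min_prominence`); this suppresses shallow bumps on the basal webbing
  that would otherwise masquerade as a basal lobe.  The central apex is
  the tip farthest from the centroid, the southern apex the tip with the
  smallest projection on the central direction, and `W` is the widest
  span between lateral apices on opposite sides of the L axis — taking
  the maximum over opposite pairs keeps `W` stable when two lobes
  protrude almost equally.

Tip-based descriptors agree with generator ground truth within 5% at
20 px/cm in the shipped checks.  The residual error is dominated by a
systematic effect of rasterization: a lanceolate tip tapers below one
pixel of width before its true apex, so the rasterized silhouette loses
the final 1–3% of each lobe and the measured spans are biased slightly
low.  Higher `ppcm` shrinks the bias; an apex-extrapolation correction
was evaluated and rejected because it overshoots on cusp-like tips.

## Scoring-board clustering

`assign_cluster()` converts each dimension to inches and snaps *up* to
the smallest grid line that contains it: a leaf is assigned the smallest
square it fits in, values exactly on a line belong to that line, values
below the smallest square map to it, and values beyond the largest
square go to an explicit overflow cell (field leaves can outgrow the
printed board).  Representatives are drawn uniformly without replacement
under a caller-supplied seed, recorded in the output for replay;
`LA_rep` is the arithmetic mean over the `k` representatives (default
`k = 2`), the unbiased choice when the aggregation formula uses a single
representative value per cluster.

The hybrid estimator has two variants:

* **representatives** (default): the model predicts each sampled
  representative's area from its measured L and W — this is the workflow
  in which representatives are handled but not photographed;
* **cells**: the model is evaluated at the cluster's own cell dimensions
  (inches × 2.54), so no leaf is measured individually at all.  This
  estimator inherits the ceiling snap's one-sided bias, which is why
  grid refinement can never increase its error on populations where area
  is monotone in (L, W): each refinement moves every cell dimension
  closer to the leaf's true dimension from above.  The refinement
  property is tested on a board extended to 23.5 inch so the widest
  leaves of the population envelope do not overflow.

## Allometric models

`fit_through_origin()` computes the least-squares slope
`a = Σx·LA / Σx²`, `RMSE` with the `1/n` denominator, and reports `R²`
as the squared Pearson correlation between observed and fitted values —
bounded in [0, 1] and comparable across predictors, which the centered
definition is not for no-intercept fits; the uncentered
`1 − SSE/Σla²` variant is available via `r2 = "uncentered"`.  Candidate
predictors are screened by a Pearson correlation t-test at p ≤ 0.01
(screening is advisory: failing predictors are excluded with a warning),
which is how the uninformative ratio `L/W` is dropped on cassava-like
data.  `select_best_model()` ranks by R² descending, ties by RMSE
ascending, then by predictor simplicity (L, W, L+W, L·W) for
determinism.  Published cassava coefficients (11.58·L, 8.54·W,
4.92·(L+W), 0.42·L·W, fitted on 111 representative leaves) ship as a
registry (`builtin_model()`) so prediction works without refitting; the
two R² columns reported alongside them in the source material are kept
as metadata, not recomputed, since the underlying per-leaf data are
unpublished.

## Evaluation metrics

For estimated totals `M_o` against benchmark totals `M_b` over n plants:
`RMSE = √(Σ(M_o−M_b)²/n)`, `MAE = Σ|M_o−M_b|/n`,
`MRE = Σ(|M_o−M_b|/M_b)/n`, plus Pearson r.  The benchmark is always the
second argument (the MRE denominator).  Reports round to 2 decimals (4
for r) for display while retaining full precision internally.  The
shipped benchmark tables reproduce every printed comparison metric at
printed precision with one exception: the greenhouse table's MRE
recomputes to 0.07 from the printed (rounded) totals, evidently having
been computed from unrounded data; it is reported as computed.  The
per-plant totals in those tables are used as given unit-free numbers —
their printed magnitudes are internally inconsistent with the stated
m²/plant unit by roughly a factor of 10, an inconsistency the package
does not attempt to resolve.

## The synthetic generator

`generate_leaf()` builds a palmate silhouette from 3–7 lanceolate lobes
radiating from a common attachment point.  Each lobe has a cartesian
width profile `w(t) = w_max·sin(πt)^p` along its axis; the silhouette is
the *radial-maximum union* of the lobes about the attachment point,
sampled on a dense angle grid (default 2048 rays) with the exact
tip angles spliced in and the axial cutoff of each ray refined by linear
interpolation.  This construction guarantees a simple polygon without a
polygon-clipping dependency; where a lobe is radially concave near its
base the union fills a small sliver, which together with the explicit
basal disc (`base_radius_frac`, default 4% of the central length) plays
the role of the webbing joining real cassava lobes.  Ground truth is
resolution-independent: area by the shoelace formula on that polygon
(cross-checked against an independent triangulation and
`pracma::polyarea` to 1e-9), `L` and `W` from the exact tip coordinates
by the same rules the tip-based measurement uses.

Defaults — 5 lobes, 200° angular spread, lobe width ratio 0.25, taper
exponent 1.5 — were chosen once to resemble cassava lobe geometry.  The
resulting silhouettes are more deeply dissected than field cassava
leaves (their area coefficient `LA/(L·W)` is about 0.25 rather than
0.42), which is why the end-to-end pipeline check fits its slope from
the measured leaves rather than assuming the published coefficient.
`generate_population()` samples leaf *records* instead: L uniform in
6.28–29.26 cm, `W = 1.36·L·(1+η)` with η ~ N(0, 0.15) rejection-sampled
into 5.00–40.58 cm, and `LA = a·L·W·(1+ε)` — the envelope observed
across 1,899 cassava leaves from three cultivars and five cultivation
conditions.  The joint (L, W) distribution is a modelling choice (none
is published); the correlated log-ratio form reproduces the qualitative
pattern that area disperses more than either linear descriptor.
`simulate_plant()` draws one morphotype per plant (lobe count, spread,
width ratio, taper fixed; size and small jitter vary per leaf), because
leaves of one genotype share their form.

What passing the synthetic checks does *not* show: robustness to uneven
illumination, shadows, petioles and overlapping or damaged leaves, to
perspective distortion, or to leaf forms outside the lanceolate-lobed
family — the renderer draws clean matte silhouettes, which is exactly
the situation the white-board field protocol is designed to approximate.

## Numerical choices and degenerate inputs

* Problem sizes in the shipped checks: 50 rendered leaves at 20 px/cm
  for image measurement, populations of 111 (model recovery, 100
  replicates), 60–80 (estimator properties, 20 replicates), one 50-leaf
  plant end-to-end.
* Seeds are mandatory wherever randomness exists (generator, population
  sampler, representative selection, rendering noise); there is no
  hidden global RNG state, and cluster outputs record their seed.
* Ties: values exactly on a board line belong to that line's cell; model
  selection breaks ties deterministically; with equal lobe lengths the
  central lobe is the one closest to the axis.
* Degenerate inputs error early with specific messages: empty scenes
  ("no leaf found"), masks that are a single row/column, zero-variance
  screens, identically-zero predictors, zero benchmark entries in MRE,
  overflow cells in the cell-based hybrid estimator.
* `fit_through_origin` is exact closed form; it is verified against a
  numeric SSE minimizer to 1e-6 relative error on 1,000 random
  instances.

## Known limitations

* Tip-based descriptors carry the negative rasterization bias described
  above (~1–3% at 20 px/cm, shrinking with resolution).
* The axis-extent method reports extents along the principal axis, which
  for leaves wider than long is the width direction; the tip-based
  method is the one aligned with the manual L/W convention.
* The cell-based hybrid estimator is deliberately biased upward (ceiling
  snap) and is intended for coarse, measurement-free field tallies; the
  representative-based hybrid is the accurate variant.
* One leaf per image; no learning-based segmentation; no petiole or
  venation analysis.
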