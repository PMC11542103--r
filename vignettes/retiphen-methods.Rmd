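---
title: "Methods: vascular phenotyping from segmentation masks"
author: "RetiPhen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vascular phenotyping from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement model behind the package: what each
stage computes, the tunable parameters and why their defaults are what they
are, what the synthetic generator does and does not emulate, and the
numerical choices that a maintainer would otherwise have to reverse-engineer
from the code.

## From masks to vessel objects

The pipeline starts where CNN segmentation ends: one binary raster per
vessel class (artery, vein) plus an optic-disc (OD) center and radius. The
pixel grid convention is fixed once and used everywhere: 0-based (row, col)
in all serialized files, origin top-left, y increasing downward; angles are
measured at the OD center in image coordinates.

1. **Thinning.** `skeletonize()` is Zhang–Suen iterative thinning: per pass,
   two subiterations delete border pixels with 2–6 foreground neighbours,
   exactly one 0-to-1 transition around the 8-neighbourhood, and the
   directional conditions, until a fixed point. The result is an
   8-connected, 1-px-wide, topology-preserving skeleton.
2. **Graph tracing.** `buildVesselGraph()` classifies skeleton pixels by
   their *reduced* neighbour count — 8-connectivity minus diagonal links
   that have an orthogonal stepping stone. This distinction matters:
   thinning output contains staircase corner pixels with three raw
   neighbours that are not junctions; on raw counts, long straight vessels
   shatter into spurious nodes. Pixels with reduced degree not equal to 2
   are node pixels; node pixels within Chebyshev distance 2 merge into one
   node at their centroid (thinning leaves branch-point clusters, not single
   pixels). Segments are maximal node-to-node paths, kept as ordered pixel
   chains.
3. **Junction artifact cleanup.** Wide junctions thin into small structures
   rather than single branch points. Three conservative passes repair this:
   self-loops shorter than 15 px (holes inside a junction) are absorbed into
   the junction; "bars" shorter than 15 px connecting two nodes of degree
   at least 3 (a junction split into two or three nearby branch pixels, up
   to a triangle) are contracted to one node; and degree-2 nodes left over
   by either pass are dissolved, re-merging their segments. 15 px is about
   one trunk width of the widest vessels we expect at fundus resolution;
   genuinely distinct junctions are separated by whole segment lengths and
   are never this close in either the synthetic trees or plausible
   vasculature.
4. **Spur pruning.** Terminal segments shorter than `minSpurPx = 10` px are
   removed at the pixel level and the graph is retraced, so a junction that
   loses its third branch dissolves cleanly; iterated to a fixed point,
   hence idempotent. 10 px suppresses thinning artifacts without deleting
   true terminal vessels at typical fundus resolution; it is configurable.
5. **Calibers.** `measureDiameters()` samples the Euclidean distance
   transform (EDT) of the class mask at every centerline pixel; the
   per-point diameter is `2 * (EDT - 0.5)`. The half-pixel term converts the
   distance to the nearest *background pixel center* into the distance to
   the mask *boundary*: a 5-px-wide bar has center-pixel EDT 3 and boundary
   distance 2.5, i.e. diameter 5. Before sampling, terminal segments are
   extended along their end direction while they remain inside the mask
   (capped at the local radius + 2 px), compensating the roughly
   half-width-per-end tip erosion that iterative thinning causes.

Node kinds follow the merged degree: 1 endpoint, 3 bifurcation, 4 or more
`crossing_candidate`. Within-class degree-4 nodes are overwhelmingly two
vessels crossing in projection, not branch points, so they are excluded from
the bifurcation count; artery–vein crossings never produce nodes at all
because each class is traced on its own raster. Loops are retained as
segments with identical end nodes.

## The 17 phenotypes

* **Tortuosity** is the distance factor: segment arc length over endpoint
  chord, 1 for a straight vessel, median over segments with chord at least
  `minChordPx = 10` px (shorter chords make the ratio unstable). The
  curvature-integral family of tortuosity measures is deliberately not
  implemented; the distance factor is caliber- and length-independent and
  is the package's single tortuosity definition.
* **Arc length of pixel chains.** A raw 8-connected chain overestimates
  length by up to 8% depending on orientation. The estimator smooths the
  chain with a moving average (window 3, configurable) and then resamples
  it about every 5 points before summing Euclidean steps; residual bias is
  below 1% across orientations (validated against straight, half-circle
  and sinusoid fixtures with analytic/quadrature arc lengths). Sub-pixel
  analytic polylines are summed directly — they need no de-staircasing.
* **Central retinal equivalents** use the revised Knudtson pairing
  (0.88 for arterioles, 0.95 for venules, `k * sqrt(w1^2 + w2^2)`): each
  segment crossing the measurement annulus contributes its mean caliber
  inside it; the six widest are combined iteratively (sort descending, pair
  widest with narrowest, carry the odd middle value). The annulus defaults
  to zone B — 0.5 to 1.0 disc diameters from the disc margin, i.e. radii
  2 to 3 OD radii from the center — the region the equivalents were defined
  for; both the constants and the annulus are configurable. With fewer than
  six qualifying vessels the equivalent is computed on what is available
  and flagged `few_segments`.
* **Temporal arcade angle.** The detailed operationalization of this
  phenotype varies across the literature; the package declares one and
  validates it against synthetic ground truth. Centerline points within
  1 to 2.5 OD radii of the disc center, on the temporal side, are split at
  the OD horizontal; each hemifield's caliber-weighted mean direction (unit
  vectors from the OD center) defines a principal arcade direction, and the
  angle between the two is reported. Temporal laterality is inferred from
  the OD offset relative to the image midline (the macula faces the image
  center) and can be overridden. A missing hemifield yields a missing
  value, never zero.
* **Diameter statistics** are the median and *population* SD over all
  per-point calibers of the class, requiring `minPoints = 50` samples —
  below that the estimates are noise and both values are reported missing.
* **Density** is the vessel fraction of an ROI, by default the disk
  inscribed in the frame minus the OD disk (the OD region contains no
  measurable vasculature and would dilute the denominator).
* **Ratios** are artery over vein, computed only when both sides are
  present. Missingness propagates explicitly end to end; no phenotype is
  ever silently zero.

## Quality control, aggregation, preparation

Images in the lowest quartile of the quality score are removed. The 25th
percentile interpolates at the Weibull plotting position `h = (n + 1) p`
(R `quantile` type 6): this retains at least 75% of distinct scores for
every n, and exactly 75 of 100 — the type-7 position can retain as few as
72.7% (n = 11), violating the retention contract. Ties at the threshold
pass. When no external score is supplied (synthetic runs), total vascular
density serves as a proxy score; density is a good image-quality proxy in
practice. A known caveat carried over from cohort practice: image quality
correlates with age, and no correction for that is applied here either.

Per subject, only the earliest visit with at least one QC-passing eye is
used; both passing eyes are averaged field-wise over non-missing values,
otherwise the single passing eye stands. Subjects with no passing image are
absent from the output, not rows of NAs.

Phenotype preparation is the GWAS-style pair: rank-based inverse normal
transformation with the Blom constant, `qnorm((rank - 3/8) / (n + 1/4))`,
average ranks for ties (the constant choice is convention; any offset in
[0, 1/2] gives nearly identical z-scores); and OLS residualization on the
covariate set (age, age squared, sex, sex-by-age, sex-by-age-squared,
spherical and cylindrical powers and their squares, categorical batch or
centre indicators, genomic PCs), with collinear columns dropped under a
warning and residuals optionally z-scored. Spherical equivalent is
spherical + cylindrical / 2 diopters.

## Correlation structure and the association battery

Phenotypic correlations are pairwise-complete Pearson; cells with fewer
than 3 complete pairs are missing. Comparing a genetic to a phenotypic
correlation matrix over the k(k−1)/2 upper-triangle pairs (136 for k = 17)
reports: Cohen's d with the *pooled* denominator
`sqrt((SDg^2 + SDp^2) / 2)` — the difference form `sqrt((SDg^2 - SDp^2)/2)`
is undefined whenever SDp exceeds SDg and is kept only behind
`dDenominator = "printed"` for auditability — a paired two-sided t test with
df = 135, the correlation of correlations, and a permutation p obtained by
randomly re-pairing the entries of the two vectors (default 10^4
permutations, seeded; p is bounded below by 1/(nperm + 1)). The permutation
scheme is a declared choice: entry re-pairing destroys exactly the
pair-level association being tested while preserving both margins.

The battery fits, per (phenotype, trait) pair, OLS on z-scored variables
(standardized effect) or logistic regression with the phenotype z-scored
(odds ratio per SD). Significance tiers follow Bonferroni thresholds
`0.05 / Ntests` and `0.001 / Ntests` with `Ntests = Nidps x Ntraits`.
Binary traits with a single observed class are reported missing under a
warning. Proportional-hazards models are out of scope by design: the
package's battery is linear/logistic only.

## The synthetic generator and what passing tests mean

`generateTree()` draws one complete binary tree per class, rooted at the
OD: the trunk enters nasally and ends at the disc center, so the two
level-1 arcades radiate from the center at exactly the requested superior
and inferior elevations — this makes the arcade-angle ground truth
(`arcadeSupDeg + arcadeInfDeg`) hold by construction inside the angle
measurement annulus. Calibers follow a Murray-type law
(`parent^k = sum(child^k)`, default exponent 3, symmetric splits).
Centerlines get sinusoidal perpendicular displacement that vanishes at
segment ends (the integer number of half-periods nearest the requested
wavelength), so branch points are exact and the per-segment tortuosity
oracle — arc length by dense quadrature over chord — describes the drawn
raster. Veins are 15% wider and 8% longer with independently jittered
sub-arcade branching, so artery–vein crossings arise naturally from raster
overlap.

Branch directions form a space-filling dyadic fan: the 2^(depth−1) terminal
branches of a hemifield get evenly spaced target directions and every
internal branch heads along the mean of its leaves. Angular order then
matches spatial order by construction, which is what keeps complete trees
self-avoiding; segment lengths grow 15% per level, as peripheral vessel
segments do, giving deep trees room. This matters because the ground truth
asserts 2^depth − 1 bifurcations per class: a generator whose branches
merge in the raster would record a truth that does not describe its own
image. Default canvases are 448 x 416 px (depth up to 3) and 576 x 512 px
(depth 4), sized to hold the fan with margin at OD radius 24 px.

The randomized validation batch draws depth 2–4, root calibers 10–16 px
(11–14 at depth 4), arcade elevations 45–62 degrees, tortuosity amplitudes
0–3 px (0–2 at depth 4) and wavelengths 35–60 px — chosen once as a
realistic spread of fundus-scale geometry. The test suite runs 200 such
images (about two minutes on one CPU).

The generator emulates: two vessel classes rooted at a disc, arcade
geometry, caliber decay, controllable tortuosity, realistic stroke widths
(1–20 px), class crossings. It does **not** emulate: photorealistic fundus
appearance, intensity profiles, segmentation noise or broken vessels,
pathology (neovascularization, beading), or the irregular, non-complete
branching of real trees. Passing recovery tests therefore demonstrates that
the measurement chain is correct on geometry it can see, not that it is
robust to segmentation failure modes; on real cohort masks the QC gate and
the per-image fault isolation in the pipeline carry that load.

One quantization limit is worth knowing: a stroke of nominal width 5.9 px
rasterizes to an effective width of 5, so for 5–6 px vessels the drawn
raster can differ from the continuous caliber-law truth by up to ~15%
regardless of measurement quality. The validation asserts the 15% agreement
for at least 90% of matched segments (observed ~97%) with a median relative
error around 5%; above 7 px the quantization band is inside the tolerance.

## Degenerate inputs and numerical details

* Empty masks pass through every stage (empty skeleton, empty graph, zero
  bifurcations); an empty class makes that class's phenotypes and the
  ratios missing.
* Missing OD makes the OD-dependent phenotypes (angle, equivalents)
  missing.
* rb-INT on constant input maps to all zeros with a warning; fewer than two
  non-missing values is an error.
* Rank-deficient covariate designs drop aliased columns with a warning;
  residuals are computed on the full column space either way.
* All randomness (generator jitter, permutations) is seeded explicitly;
  the RNG state of the caller is saved and restored, and identical seeds
  reproduce byte-identical pipeline outputs.
* Tortuosity ratios are at least 1 by the triangle inequality (arc of any
  path between fixed endpoints is at least the chord); no clamping is
  needed or applied.

## Known limitations

* Bifurcation counting is per class; if upstream artery/vein classification
  is poor, within-class crossings inflate `crossing_candidate` nodes and
  can hide true bifurcations merged across classes.
* The temporal-angle operationalization is one of several in use;
  heritability-grade stability of this phenotype is sensitive to the
  annulus and weighting choices, which is why both are exposed as
  parameters.
* The caliber floor is ~1 px; strokes below 1.5 px are traced as digital
  lines and their diameters are quantized to [1, 2] px.
* The pipeline consumes segmentation masks; nothing here fixes upstream
  segmentation errors, and the density-proxy QC fallback is only suitable
  for synthetic or pre-screened data.
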