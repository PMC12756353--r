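---
title: "Methods: classifying scoliosis from 3D vertebral centroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying scoliosis from 3D vertebral centroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineclass)
```

## The problem and the model

Adolescent idiopathic scoliosis (AIS) is a three-dimensional deformity of
the spine. The clinical standard quantifies it on radiographs (Cobb angles,
Lenke types), which costs repeated ionizing exposure in a population that is
examined every few months. `spineclass` instead starts from an ordered
sequence of 3D vertebral-body and disc centroids — the internal spinal
alignment from L5 to C7, as estimated by non-ionizing optical surface
scanning pipelines — and summarizes the deformity with continuous,
dimensionless indices plus categorical labels. It is a descriptive aid, not
a medical diagnosis.

The pipeline is deterministic:

1. **Normalization.** The centroid cloud is translated so L5 sits at the
   origin, rotated by the *minimal* rigid rotation taking the L5–C7 chord
   onto +y, and scaled uniformly so the chord measures 500 mm. This is a
   similarity transform — shape is untouched. We align with the minimal
   rotation (axis = chord × ŷ) rather than any shear because a shear would
   distort the very curvature we are about to measure; the residual
   orientation about the vertical axis is left untouched (inputs are assumed
   expressed in a patient-anatomical frame, and all reported indices are
   invariant to it in practice). "Height" is taken as the straight chord,
   not the arc length; for near-vertical spines the difference is
   second-order. Axes: +x patient's right, +y cranial, +z posterior.

2. **Interpolation.** A natural cubic spline is fitted per coordinate
   against cumulative chord length through all centroids (vertebrae and
   discs interleaved) and resampled at 1 mm arc steps. Natural end
   conditions are the conventional default when no end-slope information
   exists; their one visible cost is that curvature is forced to zero at
   the curve ends, which pollutes roughly four knot intervals (~60 mm) at
   each extreme — curvature consumers should discount those bands.
   Resampling inverts a fine (0.1 mm) cumulative-arc table by linear
   interpolation and re-evaluates the spline at the recovered parameters,
   which keeps both the sample spacing and the positions accurate to well
   below 1%; simply picking the nearest fine sample would leave up to 10%
   step jitter.

3. **Projection and regions.** The frontal projection keeps lateral
   displacement x; the sagittal projection keeps z (the view from the
   patient's left). Samples at arc positions up to the lumbar–thoracic
   transition disc (the *LT disc*, by default the disc labeled `T12/L1`,
   configurable because some spines transition elsewhere) are lumbar, the
   rest thoracic. The split is made along the *curve*, not by height, so it
   stays well-defined for decompensated spines that fold back.

## The indices

After normalization a deformity-free spine projects onto the vertical line
x = 0, so lateral displacement itself is the deformity signal. The frontal
samples are split into four quadrants (thoracic/lumbar × left/right by the
sign of x; samples exactly at 0 belong to neither side) and each quadrant
scores the **root-mean-square displacement about the vertical line**, in mm:

$$\mathrm{STD} = [\,std_{TL},\ std_{TR},\ std_{LL},\ std_{LR}\,]$$

An empty quadrant scores 0. We deliberately measure dispersion about zero,
not about the quadrant mean: a uniformly offset curve is a real deformity,
and a mean-centred standard deviation would score it as none. The
mean-centred reading remains available (`std_about_mean`) for comparison.

From the quadrant vector:

$$s = \frac{(std_{TR}+std_{LR}) - (std_{TL}+std_{LL})}{std_{TR}+std_{LR}+std_{TL}+std_{LL}} \in [-1,1]$$

$$v = \frac{(std_{TR}+std_{TL}) - (std_{LR}+std_{LL})}{std_{TR}+std_{TL}+std_{LR}+std_{LL}} \in [-1,1]$$

s is the sidedness (+1 all-right, −1 all-left), v the vertical location
(+1 purely thoracic, −1 purely lumbar). Both are undefined — reported as
`NA`, serialized as `null` — for a perfectly straight frontal projection.

Sagittal balance uses the region means of the sagittal projection,
$m_T > 0$ for a kyphotic thoracic arc and $m_L < 0$ for a lordotic lumbar
arc:

$$kl = \frac{m_T + m_L}{m_T - m_L} \in [-1,1]$$

0 is a balanced spine; kyphosis dominance is positive. All three indices
are computed on the 1 mm interpolated samples, not the raw centroids, so
long gently-curved segments weigh by their arc length.

## Thresholds and text

`default_thresholds()` holds the bucket boundaries; every boundary is
configurable because the categories are descriptive conventions, not
physiology. Severity buckets the *largest* quadrant value into half-open
intervals `[0,2.5) [2.5,4) [4,6.5) [6.5,10) [10,14.5) [14.5,∞)` mm. The
s buckets treat |s| ≤ 0.5 as both-sided (boundary inclusive). The v buckets
close the central thoraco-lumbar interval on both sides. The kl buckets
partition [−1,1] into seven categories; the upper "extreme kyphosis" bucket
is (0.65, 1] so that the seven categories are disjoint and ordered — the
only coherent arrangement of the published boundary set, whose printed
extreme-kyphosis bound overlaps its neighbours.

Sidedness and vertical labels are suppressed (reported `n/a`, omitted from
the description) when severity is "No scoliosis": localization words are
only meaningful once there is at least mild scoliosis. The numeric s and v
are still reported for audit. The description template is
`"<Severity> <side> <vertical> scoliosis with <sagittal>."` with the
sagittal clause dropped when sagittal balance is normal, and a comma before
vertical labels starting with "mainly" (matching the worked exemplars of
the classification's text style). Label strings live in one catalog
(`R/classify.R`) so clinics can re-word without touching index code.

Apexes are the extreme *centroids*: `ApexS_right`/`ApexS_left` exist only
when some centroid is displaced to that side; `ApexT`/`ApexL` are the
thoracic/lumbar centroids of largest |z| and always exist. Ties break to
the more caudal centroid.

## Concordance with the Lenke classification

For validation against Lenke records, curve types map to acceptable
vertical categories (1–2 → thoracic/mainly thoracic; 3–4 → mainly
thoracic/thoraco-lumbar; 5 → lumbar/mainly lumbar/thoraco-lumbar; 6 →
thoraco-lumbar/mainly lumbar; Normal → no scoliosis) and sagittal modifiers
to kl categories (+ → significant/extreme kyphosis; N → normal/slight
kyphosis/slight lordosis; − → nothing, it is never validated). Outputs in
the two lordosis categories form a separate `"/"` group regardless of the
patient's modifier — lordosis has no Lenke counterpart — which is the only
partition in which every patient occupies exactly one row of the published
sagittal table. Lenke-normal patients carry no modifier and are held to the
`N` expectation. Lumbar modifiers A/B/C are parsed but unused: they
reference the central sacral vertical line, which centroid data cannot
locate.

Aggregated tables feed a Pearson chi-square of independence (expected
counts from margins, df = (r−1)(c−1), upper-tail p reported at full
precision) and the overall percent agreement. The chi-square is implemented
from the O/E formula; the test suite checks it cell-loop-by-cell-loop and
against `stats::chisq.test(correct = FALSE)`.

## The synthetic generator

Clinical centroid data of this kind is not publicly shareable, so the
package ships a generator that emulates the study conditions: a 500 mm
template (18 vertebrae L5–C7, 17 interleaved discs, uniform level spacing),
a smooth sagittal profile (anterior lumbar half-sine of depth 25 mm blended
to a posterior thoracic half-sine of depth 30 mm — slightly
kyphosis-dominant, kl ≈ +0.09, i.e. a normal balance), and a lateral curve
built from two quarter-sine lobes peaking exactly at the chosen apex
vertebra over a 180 mm span (≈six vertebral levels, a typical structural
curve) and vanishing at both spine ends so the L5–C7 chord — the
normalization reference — is unaffected. Optional independent Gaussian
jitter (default 0.5 mm, sub-millimetre centroid-extraction precision) is
added per coordinate. Everything is reproducible from an integer seed.

The half-sine shape was chosen over polynomials because its quadrant RMS
has a closed form (amplitude/√2 over the support), giving analytic oracles
for the index tests. Two ground truths accompany each spine: the generating
parameters, and the *realized* frontal apex — the centroid of the jittered
anatomy with the largest lateral offset from the L5–C7 chord, computed by
direct vector rejection, independently of the pipeline's rotation code.
Recovery tests target the realized apex because the jitter is anatomical
variability of the synthetic patient: near the curve's flat peak,
neighbouring centroids differ by only ~2% of the amplitude, so the most
displaced centroid of the actual anatomy legitimately sits one position
away from the nominal apex level, and the pipeline is correct to report it.

What the generator does *not* emulate: axial vertebral rotation (rib hump),
non-uniform vertebral spacing, double-structural geometries beyond a simple
compensatory second lobe, and spatially correlated measurement error.
Passing recovery tests therefore demonstrate the pipeline's geometric
correctness, not clinical accuracy on real scans.

## Numerical choices and edge cases

* Coincident L5/C7, or coincident consecutive centroids, raise classed
  degenerate-geometry errors; malformed files raise validation errors
  naming the offending row.
* Curvature is computed per projection by three-point finite differences
  of the parameterization-invariant planar formula
  $\kappa = |d'h'' - h'd''| / (d'^2+h'^2)^{3/2}$ on the 1 mm grid, with
  one-sided quadratic fits at the two endpoints. On circular-arc test
  spines the interior error against 1/R is below 1%.
* Curvature smoothing is off by default; an odd-width moving average is
  available because upstream strain-normalization conventions differ.
* Undefined indices propagate as `NA` and serialize as JSON `null`; they
  are never coerced to 0.
* Reports embed a deterministic digest of the threshold configuration so
  that archived results can be traced to their boundaries.

## Problem sizes in the test suite

The suite exercises cohorts of 100 spines for recovery checks, 200 for the
mirror-antisymmetry property, a 0–60 mm amplitude grid for severity
monotonicity, 1,000 random contingency tables for the chi-square oracle,
and circular arcs of radius 100–1000 mm for curvature fidelity; the whole
suite runs in well under five minutes on a single CPU.

## Known limitations

Per-centroid rotation angles are read and stored but never used; no Cobb
angles are computed; the central sacral vertical line (hence Lenke lumbar
modifiers) is out of reach of centroid-only input; and thresholds are
descriptive defaults awaiting clinical calibration, which is why every one
of them is a configuration value rather than a constant.
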