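---
title: "Automated fetal biometry and amniotic fluid assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated fetal biometry and amniotic fluid assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalbiom)
```

## The measurement problem

A routine obstetric screening scan produces short free-hand cine-loops
swept through the fetal head, abdomen, femur, and the amniotic fluid
pockets. From these, clinical practice extracts four biometric lengths —
head circumference (HC), biparietal diameter (BPD), abdominal
circumference (AC), femur length (FL) — plus the single deepest pocket
(SDP) of amniotic fluid, and derives estimated fetal weight (EFW) and
gestational age (GA). The sonographer's job has two distinct parts:
*choosing* a standard plane inside each sweep (a quality judgement codified
by the ISUOG criteria) and *measuring* on the chosen plane (caliper
placement). `fetalbiom` automates both, given per-frame instance
segmentations from any external model; the package itself ships no trained
network and treats segmentation as a pluggable backend contract.

## Plane selection

Every frame of a loop is scored with a composite

$$S = w_q Q + w_z Z + w_c C, \qquad w_q + w_z + w_c = 1,$$

where $Q$ is the mean of the plane's criterion probabilities (head:
cerebellum not visible, cavum septi pellucidi, posterior horns, symmetry,
thalami; abdomen: kidneys not visible, portal sinus, stomach bubble,
symmetry), $Z$ is the zoom term, and $C$ the backend's detection
confidence. The highest-scoring frame is measured; exact ties go to the
earliest frame so selection is deterministic and permutation-invariant.
Choices behind this form, all configurable through `fb_config()`:

* **Functional form.** A weighted sum rather than a lexicographic rule: it
  is monotone in every component, tolerates a single failed criterion when
  everything else is excellent, and has an obvious neutral default
  (equal thirds). No published weighting exists for this score, so the
  weights are exposed rather than hidden.
* **Zoom.** The automatable version of "structure occupying more than half
  of the image" is the occupied-area fraction. It enters the score as a
  binary conformity indicator by default (the criterion is binary);
  `zoom_mode = "raw"` substitutes the fraction itself. Thresholds are
  per-structure: 0.5 for head and abdomen, but 0.02 for the femur — an
  elongated bone geometrically cannot cover half the image, so its
  threshold is set to what a well-zoomed femur actually occupies.
* **Femoral quality.** The femoral plane has no criterion classifier; its
  quality is derived entirely from the mask: the zoom ratio and the bone's
  angle to the horizontal, conforming when strictly below 45 degrees.
* **Caliper-placement criteria.** The checklist items about correct caliper
  and ellipse placement are outcomes of this pipeline's own deterministic
  caliper computation, so they are recorded as satisfied by construction.

## Geometry

**Contours.** The outer boundary of a mask is traced on the largest
8-connected component at iso-level 0.5 of the occupancy grid
(marching-squares interpolation). The 0.5-level is the natural sub-pixel
estimate of a filled structure's edge: it runs half a pixel outside the
outermost occupied pixel centers.

**Ellipse fit.** HC and AC come from a direct least-squares conic fit with
the ellipse-specificity constraint $4AC - B^2 = 1$, in the numerically
stable partitioned (block-eigenproblem) formulation, after centering and
isotropic scaling of the points. The classic single generalized
eigenproblem is ill-conditioned for near-circular data, which fetal heads
are. The fit is equivariant under translation and rotation and recovers
noise-free planted ellipses to 1e-6 relative; BPD is the full minor-axis
diameter $2b$ with no outer-to-inner skull-table correction.

**Circumference.** The perimeter is $4 a E(e^2)$ with the complete elliptic
integral of the second kind evaluated by the arithmetic-geometric mean, not
a series approximation; the circle limit gives $2\pi r$ and the degenerate
flat limit $4a$ exactly, which makes the implementation testable against
adaptive quadrature at 1e-10 relative.

**Femur.** FL is the long side of the minimum-area rotated rectangle of the
occupied pixels (rotating calipers over the convex hull). The primitive
reports pixel-center extents — `max - min` of pixel centers, with a
deterministic tie rule (axis closest to horizontal) when the minimal
rectangle is square. The *pipeline* then places the femur caliper tips on
the structure boundary, half a pixel beyond the outermost centers at each
end, so FL uses the same iso-0.5 boundary convention as the contour-based
HC and AC. Without that half-pixel pair a rasterized bone of continuous
length $L$ measures systematically $L - 1$ pixels.

**Pocket depth.** SDP is the vertical extent of the pocket's axis-aligned
bounding box (`max row - min row`), deliberately so even for tilted
pockets; the column of the deepest single vertical chord is reported only
to position the display calipers. Depths convert with the row spacing, so
anisotropic pixels are acceptable here; circumferences and femur lengths
mix both image directions and refuse anisotropic spacing (no silent
averaging).

**Units.** Everything internal is centimeters. DICOM PixelSpacing is
row-then-column in millimeters and is converted exactly once at ingest —
the standard guard against the classic factor-10 error.

## Clinical formulas

EFW uses the 3-parameter Hadlock log-polynomial
($\log_{10} EFW = 1.335 - 0.0034\,AC\,FL + 0.0316\,BPD + 0.0457\,AC +
0.1623\,FL$, inputs in cm, output in grams); EFW is computed only when AC,
FL and BPD are all present — no fallback formulas. GA uses the Intergrowth
late-pregnancy formula
($\ln GA = 0.03243 (\ln HC)^2 + 0.001644\, FL \ln HC + 3.1813$, GA in
days), with HC and FL fed in millimeters by default (the convention of the
formula's source; configurable). A caveat worth repeating from
`?formula_config`: the intercept 3.1813, as printed, yields implausibly low
gestational ages for typical mm-scale inputs (about 102 days at
HC = 250 mm, FL = 50 mm). The package implements the printed value rather
than silently recalibrating, and exposes the coefficient for override.

AFV categories use strict inequalities: SDP < 2 cm is oligohydramnios,
SDP > 8 cm polyhydramnios, the closed interval between them normal.
Fetal-growth-restriction percentile classification requires external
growth-standard tables and is exposed only as a hook, not implemented.

## The phantom: what it emulates and what it does not

`phantom_spec()` builds synthetic loops with exact ground truth: a
rasterized head/abdomen ellipse or femur capsule whose apparent scale
varies across frames and peaks at a planted best frame, or rectangular
amniotic pockets of known depth spread across a sweep. Planted criterion
flags are all-true only at the best frame (elsewhere exactly one flag is
false, cycled deterministically) and the confidence profile peaks there
too, so best-frame selection has a testable right answer. Defaults emulate
a late-pregnancy acquisition at 0.05 cm/px on a 256x256 field: head
120x90 px (BPD 9 cm, HC about 33 cm), abdomen 115x100 px, femur
140 px (7 cm) at 20 degrees, pockets of 2.8/4.2/5.6 cm.

Deliberate simplifications: criterion flags are metadata, not rendered
anatomy — the pipeline consumes classifier probabilities, so testing
selection logic needs controllable flags, not realistic thalami. Speckle is
optional unit-mean multiplicative gamma noise; there is no wave or ray
modeling, no shadowing, no twins. Consequently, passing phantom tests
demonstrates that the *measurement and selection* stages are correct given
segmentations of stated quality; it says nothing about how any real
segmentation model performs on clinical images.

Imperfect segmentation is emulated by morphological degradation of the
oracle masks (erosion or dilation by a disc of radius $k$ pixels). The
end-to-end recovery study measures 200 seeded cases — 50 per loop kind with
randomized geometry (head semi-major 105-120 px, axis ratio 0.72-0.78;
abdomen 105-120 px, ratio 0.85-0.95; femur 120-150 px at up to 40 degrees;
3-4 pockets with maximum depth 4.8-6.4 cm) — under a stratified degradation
design: the radius cycles 0, 1, 2 over case seeds (balanced thirds) with
the direction drawn at random. Stratification keeps the study's summary
medians a property of the conditions rather than of the luck of an
unbalanced draw. Under these conditions the median absolute relative error
of every parameter stays below 2% and the planted best frame is selected in
every loop; a disc of radius $k$ shifts every boundary by $k$ px, so the
$k = 2$ stratum alone carries errors around 3-4% on a 120-150 px femur —
an inherent property of degraded masks, not a pipeline defect.

## Annotation reconstruction

Retrospective ground truth lives in images as burned-in overlays. The
package renders such overlays onto phantom frames (caliper crosses, a
24-dot measurement ellipse, text glyphs) and recovers them: palette-matched
connected components become caliper candidates, gated by normalized
cross-correlation against cross/x templates (a solid palette-colored region
has zero shape variance in its bounding box and is rejected); dot-cluster
centroids feed the ellipse fitter with one reject-refit round whose inlier
rule is a Tukey fence on radial residuals ($\le q_{75} + 1.5\,IQR$, floored
at 2 px) — chosen because stray dots drag the initial fit and inflate
*all* residuals, defeating cutoffs scaled by the median alone. Measurement
text parsing is regex-driven ("ACRONYM value unit", decimal comma or
point, `31w4d` gestational ages) with unknown acronyms skipped under a
warning; the OCR engine itself is an external interface. Default overlay
colors (saturated yellow/green/cyan/magenta, +-40/255 per channel) are
documented guesses validated only on synthetic renders — vendors vary, so
the palette is configuration.

## Agreement statistics

Method comparison uses: mean absolute error with its SD; Bland-Altman bias
and 95% limits of agreement `bias +- 1.96 sd(d)` with the sample SD, in
absolute or percentage form (the percentage denominator is the pair mean,
the standard choice; 1.96 is a constant of the method, not a configurable
z); the one-way random-effects ICC(1,1) from ANOVA mean squares, which for
two raters is $(MS_B - MS_W)/(MS_B + MS_W)$ — for balanced two-rater data
this coincides with the mixed-model estimate, and a two-way
absolute-agreement variant is available; the paired Wilcoxon signed-rank
test (zeros dropped, mid-ranks for ties, exact null up to 25 untied
differences, normal approximation with continuity correction beyond — the
test is sometimes loosely called "rank sum" in clinical reporting, but the
paired design calls for the signed-rank form); sensitivity/specificity with
the full 2x2 table; and Dice/IoU for masks, with two empty masks scoring 1
by convention.

## Numerical conventions and degenerate inputs

* Angles live in (-90, 90] measured from the image horizontal; positive
  slopes toward increasing row index.
* An empty candidate list is a *no-plane-found outcome*, not an error:
  partially complete examinations produce partial, valid reports, and EFW/GA
  appear only when their inputs do.
* NaN is forbidden in serialized reports; absent values are explicit JSON
  nulls. Number formatting is fixed so identical inputs produce
  byte-identical reports.
* Ellipse fitting refuses fewer than 5 points, collinear or coincident
  scatters, and non-elliptical constrained solutions, with classed errors.
* Masks smaller than the 8-point contour minimum (single pixels) are
  reported as empty structures.
* Frames within a loop must share dimensions and spacing; mismatches are
  rejected rather than resized, because resizing silently changes the
  pixel spacing.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run, per invocation: the 200-case
phantom study above (20 frames of 256x256 px per loop), 100 annotated
frames for the render-to-detect round trip, 100-point coefficient grids for
each clinical formula against frozen 50-digit reference values, a 50-point
ellipse-circumference grid against adaptive quadrature, and ICC Monte-Carlo
recovery at 500 subjects per variance ratio. These sizes give stable
medians and rates while keeping a full run in well under a minute each.

## Known limitations

Segmentation and criterion classification quality are entirely the
backend's; the oracle backend only bounds what perfect and
uniformly-degraded segmentations yield. The DICOM reader covers
uncompressed little-endian transfer syntaxes (explicit and implicit VR)
only, and video containers are not read directly — export frames or DICOM.
The SDP bounding-box definition overstates the depth of strongly tilted
pockets by design. The Intergrowth intercept caveat above applies to any GA
this package reports with the default coefficients.
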