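---
title: "Methods: multi-angle polarized PSR collagen quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-angle polarized PSR collagen quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrcap)
```

## The measurement problem

Picrosirius red (PSR) enhances the natural birefringence of fibrillar
collagen: under crossed linear polarizers, collagen fibers appear bright
against an extinguished background.  The brightness of an individual
fiber, however, depends on its in-plane orientation $\varphi$ relative
to the polarizer transmission axes.  For ideal crossed polarizers the
transmitted intensity of a fiber of amplitude $A$ at stage rotation
$\theta$ follows

$$ I(\varphi, \theta) = A \, \sin^2\!\big(2(\varphi + \theta)\big), $$

so fibers aligned with either polarizer axis are extinguished entirely.
A single polarized image therefore under-reports collagen.  The remedy
implemented here is the multi-angle protocol: the slide is rotated
counterclockwise in increments $\Delta\theta$, one image is captured per
angle over a full revolution, each frame is background-corrected with a
blank-slide image, co-registered back to the $0^\circ$ reference frame,
and the stack is fused into a composite that keeps, per pixel, the
maximum grayscale intensity across frames.  Collagen in the fibrous cap
(the region between the arterial lumen and the necrotic core) is then
quantified two ways: summed/averaged grayscale intensity, and the count
of "collagen-positive" pixels whose intensity exceeds a threshold
(600 counts by default on 12-bit data).

The composite retention of a fiber over a schedule
$\Theta = \{0, \Delta\theta, 2\Delta\theta, \dots\}$ is
$\max_{\theta \in \Theta} \sin^2(2(\varphi + \theta))$.  For
$\Delta\theta = 60^\circ$ the doubled angle steps by $120^\circ$, and the
worst case over $\varphi$ is exactly $\sin^2 60^\circ = 0.75$
(`composite_retention()` verifies this on a $0.1^\circ$ grid).  This is
why pixel *counting* is robust to coarse increments: any fiber bright
enough that $0.75\,A$ clears the threshold is counted identically at
$\Delta\theta = 2^\circ$ and $60^\circ$, even though its recorded
*intensity* can differ by up to a third.  It is also why half-rotation
schedules suffice up to acquisition error: $\theta$ and
$\theta + 180^\circ$ give identical responses, so the angles below
$180^\circ$ already sample every distinct polarization phase.

## The synthetic phantom

No imaging data from the original cadaver-heart material is deposited,
so the package ships a generator (`phantom_spec()`, `build_phantom()`,
`render_polarized()`, `render_blank()`, `render_brightfield()`) whose
output stands in for an acquisition session.  The phantom is an artery
cross-section: a circular lumen, a fibrous-cap annulus populated with
rectangular birefringent fibers, and a necrotic core whose inner
boundary terminates the cap.  Each fiber carries an orientation
$\varphi \in [0, 180)$ and an amplitude in counts; rendering at stage
angle $\theta$ rotates the geometry counterclockwise about the image
center, applies the $\sin^2$ law above, adds a background level, a
gentle illumination gradient (shared with the blank frame), and
Gaussian read noise, then clips to $[0, 4095]$ and quantizes — the
12-bit camera contract.

Default parameter choices, made once on realism grounds:

* **Frame**: $650 \times 515$ px at 8.7 µm/px — the study camera
  geometry (1300×1030 px, 230 px/mm = 4.35 µm/px; `um_per_px(230)`) at
  half resolution, the desk scale the acceptance protocol allows.
* **Geometry**: lumen radius 110 px (~0.96 mm), cap annulus 110–160 px
  (~435 µm thick, a thick fibrous cap), core outer boundary 205 px.
* **Fibers**: 250 rectangles of 30 × 6 px (~260 × 50 µm fiber bundles),
  amplitudes uniform in 1000–3500 counts — a collagen-rich cap whose
  fibers sit well above the 600-count threshold even at worst-case
  composite retention ($1000 \times 0.75 = 750 > 600$), matching the
  "bright phantom" condition of the angular-increment benchmarks.
* **Noise**: additive Gaussian, SD 30 counts; background level 120
  counts with a ±10 % corner-to-corner gradient.  Stage-angle jitter
  and re-centering shift default to 0 (the protocol re-centers the
  lumen); they can be enabled to exercise the registration refinement.
* **Fiber color**: one orange tint whose BT.601 luma is exactly 1, so a
  fiber's grayscale value equals its polarized intensity.  Hue carries
  no information in this analysis (grayscale only), so the green/orange
  variation of real serial sections is emulated only through the scalar
  `thickness_scale` on amplitudes.

**Rasterization is area-weighted (antialiased).**  A camera pixel
integrates irradiance over its footprint, so edge pixels receive the
covered fraction of the fiber intensity.  This matters: with a hard
in/out rasterizer the rendered footprint jitters by ±½ px as the stage
rotates, and a 180-frame maximum composite then dilates every fiber by
its perimeter — a pure aliasing artifact that inflated the
$\Delta\theta = 2^\circ$ vs $60^\circ$ pixel-count comparison by ~6
percentage points in development builds.  Physical acquisitions do not
alias this way.

What the generator does **not** emulate: PSR staining chemistry,
wavelength-dependent retardance (the $\sin^2$ law is the ideal
monochromatic crossed-polarizer form), Poisson photon statistics, tissue
autofluorescence, sectioning artifacts beyond a scalar thickness factor,
or camera white balance.  A green test on the phantom therefore
establishes that the *pipeline arithmetic and geometry* behave as
specified — not that the method's tissue-level numbers transfer to real
histology.

## Registration

Each frame is coarse-aligned by rotating it by minus its known stage
angle about the image center (`coarse_align()`), after which only a
small residual rigid transform remains.  The residual translation comes
from FFT phase correlation with parabolic sub-pixel peak interpolation;
rotation+translation are then jointly refined by maximizing normalized
cross-correlation over a bounded search (±5°, ±50 px by default) on a
decimated pyramid, polished by parabolic interpolation
(`estimate_transform()`).  The coarse rotation and the residual are
composed so each frame is resampled exactly once (bilinear), and pixels
mapped from outside the frame are flagged in a validity mask that
downstream statistics respect.

Two numerical choices deserve explanation:

* **Similarity channel.**  Raw-intensity NCC between frames at
  different stage angles is intrinsically low even at perfect alignment,
  because the $\sin^2$ law modulates each fiber differently (at a
  $45^\circ$ phase offset the fiber-intensity correlation is analytically
  about 1/3).  Correlation is therefore computed on *structural* images —
  intensity saturated at a quarter of the 99.5th percentile, i.e.
  near-binary fiber footprints.  Honest registrations of default
  phantoms score 0.80–0.96 on this channel; the acceptance floor is 0.7,
  with one retry at doubled search bounds before a frame is rejected
  (the error names the failing angles).
* **Parsimony guard.**  A nonzero residual rotation is accepted only if
  it improves the structural NCC by more than 0.005 over the
  translation-only solution, and sub-resolution residuals
  (<0.02°, <0.05 px) are snapped to zero rather than resampling the
  frame.  Measured on phantoms, spurious rotation "gains" from the
  modulated similarity surface are ≤0.003 while true rotations ≥0.3°
  gain ≥0.009, so the guard rejects noise without costing recovery
  accuracy (simulated transforms are recovered to ≤0.5 px / ≤0.2° RMS).

## Compositing, cap geometry, quantification

`max_composite()` takes the maximum on the grayscale (BT.601 luma)
projection and copies the winning frame's RGB triplet, so composite
colors are realizable colors of some input; ties go to the lowest
acquisition angle for determinism.  Grayscale values are kept
real-valued — no re-quantization before thresholding.

The cap region is defined from the lumen and core contours (inputs, as
in the original protocol; the phantom supplies its ground-truth
contours).  Rays at one-degree intervals emanate from the lumen
centroid (an explicit override point is accepted); a degree sector is
active when its ray (cast at $d + 0.5^\circ$) meets the core contour.
Rather than rasterizing 360 ray polygons, `cap_sector_mask()` bins
pixels by polar angle about the center — geometrically equivalent but
guaranteeing an exact partition with no double-counted boundary pixels
(per-degree results sum to totals *exactly*).  A cap pixel must lie
outside the lumen boundary and closer than the first ("leading") core
crossing along its own polar direction; when a ray crosses an irregular
core contour several times, the nearest crossing terminates the cap by
declared convention.

"Above the threshold" is implemented as strictly greater-than, making
the boundary case testable: pixels {599, 600, 601} yield one positive
pixel at threshold 600.  The default 600 is a configuration constant,
not re-derived at run time; `lumen_reference_stats()` reports the
lumen-area mean/SD for users who want to re-derive a threshold for
their own material (the original 600 was chosen from lumen statistics
of 300 ± 232 counts, not by an explicit formula).  The per-degree
"average" divides by sector area; both sums and areas are emitted so a
positive-pixel-normalized mean can be formed if preferred.

## Study drivers and their scaled-down defaults

`run_angle_study()` reproduces the angular-increment design: increments
{2, 6, 12, 44, 60}°, ranges full/low/high — 15 composites per sample —
quantified on identical masks, with ratio tables against the
$\Delta\theta = 60^\circ$ full-range reference and half-vs-full.
`run_threshold_study()` sweeps the positive-pixel threshold 0–1000
counts on the smallest and largest increments, reporting counts
relative to no threshold.  `run_repeatability_study()` simulates 30
serial sections whose amplitude scale varies with a chosen coefficient
of variation (section thickness modulates birefringent brightness) and,
optionally, a linear cap-thinning trend; thresholded counts respond far
less than mean intensity to thickness variation, and respond
monotonically to true cap thinning — the responsivity contrast the
method is designed around.  The multi-operator reproducibility study
cannot be simulated faithfully; `operator_agreement()` provides the
declared analog (re-acquisition with a different jitter/noise stream)
and emits both readings of the agreement metric — pixel-wise overlap
relative to the average positive count, and the total-count ratio —
since the original definition is ambiguous between them.

The test suite runs all drivers on reduced phantoms (200×160 px, coarse
increments) to stay within seconds; the acceptance suite runs the
full-size stated world, where the $\Delta\theta = 2^\circ$ schedule's
180 frames dominate the runtime.

## Known limitations

* The blank-slide background's spatial structure is not characterized
  in the source protocol; a smooth linear gradient is assumed.
* Background subtraction is per-channel with clamping at zero
  (negative light is unphysical); whether the original subtracted
  before or after grayscale conversion is not stated — subtraction must
  precede compositing here, which operates on RGB.
* The registration algorithm and quality metric of the original MATLAB
  implementation are unspecified; the choices above are declared, not
  inferred.
* Fibers whose rectangle overhangs the cap annulus by up to half a
  length are kept (centers are constrained to the annulus), mirroring
  fibers crossing histological boundaries.
* Very bright fibers clip channel-wise at 4095 (the red channel first,
  at intensities above ~2400 counts), which compresses *intensity*
  totals but cannot affect counting at thresholds ≤ 2400.
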