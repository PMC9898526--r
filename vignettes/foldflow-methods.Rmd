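---
title: "Measuring and modelling curvature-tension driven fold deepening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling curvature-tension driven fold deepening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldflow)
```

## The model

During epithelial fold formation, a tissue strip under in-plane tension $T$
experiences a net inward (Laplace) force per unit length of magnitude
$\kappa T$, where $\kappa$ is the local curvature of the fold front seen in
a transverse (medial-lateral $\times$ depth) section. When this force is
balanced only by a normal dissipative drag $-\mu v_n$, the front obeys

$$\kappa T(t) - \mu\, v_n = 0 \qquad\Longleftrightarrow\qquad
  v_n = \frac{\kappa\,T(t)}{\mu},$$

a curvature flow with a time-dependent mobility. The thin-strip idealization
is justified when tissue thickness (~10 µm) is small compared to the front's
radius of curvature (~300 µm); bending stiffness and buckling are outside
the model. Two experimentally checkable consequences follow:

1. **Collapse.** Deepening speed plotted against the product
   $\kappa \cdot T$ falls on a single line through the origin whose slope is
   $1/\mu$; the coefficient of determination of that origin-constrained fit
   measures how well the law holds.
2. **Homogenization.** Because more curved regions deepen faster, curvature
   becomes spatially more uniform while its mean grows.

Tension is never measured absolutely: the initial recoil velocity after
laser ablation is proportional to tension only up to a dissipation
prefactor, so $T$ is carried in recoil-velocity units (µm/s) and the
calibration constant is absorbed by the fitted slope. $\mu$ is therefore
recovered in hybrid units, (µm/s · µm⁻¹) · h / (µm/h).

## The measurement operators

All operators mirror how the quantities are measured on real movies:

* **Curvature** at a front position is the inverse circumradius of the
  circle through the point and the two points located 22.5 µm away along
  arc length on either side (`localCurvature()`, with
  `circumcircleCurvature()` as the primitive). The estimator is exact for
  triplets on a circle and has $O(h^2)$ error on smooth curves. Curvature is
  signed positive when the osculating center lies on the +z (inward) side,
  so deepening under positive tension corresponds to positive curvature.
  The 22.5 µm half-span is measured along arc length (the only convention
  that stays meaningful on steep fronts), in physical µm, before any
  percent normalization.
* **Normal deepening speed** intersects the local normal (perpendicular to
  the chord between the two flanking triplet points, oriented +z-ward) with
  the piecewise-linear front of the next frame (`normalSpeed()`).
* **Registration** maps ML positions to percent with per-side affine scales
  (midline 0%, left/right macrochaetae -100%/+100%: the three anchors need
  not be symmetric), corrects tilts up to 15°, anchors developmental time
  at the last microchaete division = 22 hAPF, and rescales 29 °C intervals
  by 1.27 (`registerSpace()`, `registerTime()`).
* **Material tracking**: each labeled Position_ML moves along the straight
  ray from its initial position toward a convergence center
  (`trackTowardCenter()`). The center's depth is a required input: it is an
  anatomical datum (the adult neck position) that cannot be derived from
  the fronts themselves. The synthetic studies use the flank-circle center.
* **Temporal smoothing** is a centered boxcar, 1 h 45 min for
  curvature/speed profiles and 2 h for recoil proxies, truncated at the
  series edges (`smoothTime()`, `slidingAverageByDevTime()`).
* **Ensemble filtering** removes (time, position) cells covered by fewer
  than 5 animals or with curvature sem above 0.002 µm⁻¹
  (`ensembleAverage()`); sem is sd/√n over animals.
* **Recoil velocity** is the least-squares slope of the displacement trace
  in the 1-7 s window (0.25-1.25 s for circular-ROI traces). A regression
  is used rather than a two-point difference because it is noise-robust and
  reduces to the difference quotient on linear traces; the two-point
  variant remains available for sensitivity checks
  (`initialRecoilVelocity()`).
* **Threshold rule**: positions with initial curvature below
  0.00015 µm⁻¹ take the tension curve measured in flattened animals,
  others the non-flattened curve (`assembleTensionProxy()`).
* **Product error**: the sem attached to $\kappa T$ is
  $\bar\kappa\sigma_v + \bar v\sigma_\kappa + \sigma_v\sigma_\kappa$,
  exactly, cross term included (`productError()`).

## The forward simulator

`simulateFlow()` integrates the flow with explicit Euler steps. Each node
carries the discrete curvature vector of its neighbor triplet (pointing at
the circumcenter), which is orientation-free and works identically for
open pinned strips and closed rings. Three numerical safeguards matter:

* **Step control.** Besides the advective bound
  $\Delta t \le c\,\Delta x_{\min}/v_{\max}$, the step obeys the parabolic
  stability limit $\Delta t \le c\,\Delta x_{\min}^2 \mu / (2T)$: the flow
  linearizes to diffusion with $D = T/\mu$, and an explicit scheme bounded
  only advectively develops sawtooth instability. The default safety
  fraction is $c = 0.2$ with $\Delta t_{\max} = 0.05$ h.
* **Per-step uniform resampling** prevents node clustering where the flow
  compresses the curve; it is skipped when the velocity field is exactly
  zero so that zero tension is exactly the identity.
* **Input resolution.** The initial polyline should be sampled at least as
  densely as the integrator's node count; upsampling a coarse polygon
  creates sub-chord jaggedness that the flow then amplifies.

Pinned endpoints emulate the mechanical continuity with the flanking
tissue, but they are an artifact of the finite simulated strip: a
flattening boundary layer grows diffusively from each pin, reaching about
$\sqrt{2(T/\mu)t} \approx 110$ µm over a 6 h run. All measurement defaults
therefore keep a two-diffusion-length margin (225 µm) between tracked
positions and the strip ends. Curvature homogenization is summarized at
tracked material positions (`homogeneityCV()` with `center`/`anchorX`):
a fixed arc-length window instead loses curvature through its edges by
advection and shows a spurious early dip.

## The synthetic study

No imaging data ships with the package, so `studyConfig()` defines a fully
specified in-silico study whose ground truth is known. The defaults are
chosen to match the printed scales of the system being emulated:

| parameter | default | rationale |
|---|---|---|
| geometry | `flattened_medial` | medial coverslip contact flattens the medial front |
| arc radius | 300 µm | the front's initial radius of curvature |
| flat half-width | 100 µm | coverslip contact region |
| span (arc length) | 900 µm | tracked region extends to ~±300% ML |
| macrochaetae | ±150 µm | sets the ±100% registration scale |
| tension ramp | 0.2 → 0.6 over 14-24 hAPF | recoil velocities rise through folding; ablations cover 14-24 hAPF, wider than imaging, so the 2 h window never truncates inside 16-22 hAPF |
| µ | 4 × 10⁻⁴ | gives deepening speeds of a few µm/h |
| landmark spacing / noise | 15 µm / 0.5 µm sd | landmarks placed ~every 20 µm, with placement jitter |
| frames | every 0.25 h, 16-22 hAPF | the imaging window |
| proxy noise | 5% log-normal, unit mean | multiplicative keeps tension nonnegative |
| animals | 10 | typical ensemble size |
| seeds | master + animal index | subsetting never changes an animal |

Inter-animal dispersion of µ and the tension scale is exposed
(`muCv`, `tensionCv`) but defaults to zero: that variability is not
characterized, and the reference study tests the pipeline, not a guess.

What the generator does **not** emulate: optical blur and anisotropic
segmentation error (noise is i.i.d. Gaussian per landmark), front
digitization by a human tracer, drift or registration failure, basal-front
inaccuracy, or any cell-level mechanics. Passing the recovery test
therefore shows the *pipeline* is unbiased under its own assumptions at
realistic noise levels - not that those assumptions hold on real movies.

### Pairing curvature with speed

The speed measured between frames $t$ and $t+\Delta t$ is a mean over the
interval, while curvature and tension drift within it. The profile builder
therefore records, by default, the speed at the interval midpoint together
with the mean of the two frame curvatures and the tension at the midpoint
(`pairing = "midpoint"`), which is unbiased to first order in $\Delta t$.
The forward convention (everything at $t$) is available as
`pairing = "forward"`; with the default smoothing both agree to about 2%.

### What the reference study yields

With the defaults and seed 1, the pipeline keeps 730 (time, position)
cells after filtering (1.9% removed), and the origin fit recovers
µ within ~2% at $R^2 \approx 0.92$. Noise-free runs with 5 µm landmarks
recover µ within 0.1%; at the realistic 15 µm landmark spacing the
circumcircle estimator carries a few-percent sampling scatter
(the 22.5 µm triplet rides on interpolated chords), which attenuates the
fitted slope by about 1-2% - well inside the 10% acceptance band.

## Image operators

* **Apical surface**: per (laterally downscaled) pixel, an along-z running
  variance profile is thresholded at 30% of its maximum; the surface is
  the variance-weighted centroid of the most apical high-variance run. The
  centroid is used instead of the raw variance argmax because a variance
  filter across a thin bright band peaks on the band's two flanks; the
  centroid of the enclosing run recovers a symmetric band's center
  exactly. The variance window (default 9 slices) should cover the bulk of
  the band. The coarse map is bilinearly upscaled (`apicalZMap()`), and
  any channel can then be projected at a signed slice offset from the
  surface (`projectOffset()`, offsets clamped with a warning).
* **Fibers**: background subtraction is a grayscale opening with a disc
  element (the rolling-ball algorithm is a morphological opening; exact
  plugin parity is not needed for property-level tests, and EBImage's
  morphology is normalized to [0, 1] internally). The binarized image is
  thinned (Zhang-Suen, implemented here - no installed package provides
  thinning), junction pixels (crossing number ≥ 3) are removed together
  with their 8-neighborhood (arm stubs otherwise stay diagonally
  connected), and each remaining 8-connected path becomes a segment whose
  length is the distance between its endpoints and whose orientation is
  the endpoint angle folded into [0°, 90°] relative to the ML axis.
  Segments of length ≤ 0.8 µm are dropped. The binarization threshold is a
  required operator input: it is subjective on real stainings and no
  default is presented as correct.
* **Orientation summaries** are length-weighted means over fibers whose
  midpoints fall in the ROI (`weightedMeanOrientation()`).
* **Intensity vs curvature**: samples are binned by curvature in
  0.001 µm⁻¹ bins and each bin's mean is normalized by the unbinned
  all-sample mean, making the count-weighted mean of normalized bins
  exactly 1 (`intensityVsCurvature()`). When testing whether intensity
  varies along the ML axis, the ANOVA groups are the curvature bins.

## Statistical conventions

Welch's unequal-variance t test (two-sided) compares conditions per
time point; p-values are banded `none` (p > 0.05), `weak`
(0.01 ≤ p ≤ 0.05), `strong` (p < 0.01). The banding boundaries are not
defined by the convention being mirrored ("p > 0.05", "p < 0.05",
"p < 0.01" leave 0.05 and 0.01 open); both boundary values are assigned to
`weak`, i.e. `strong` is strict. No multiple-comparison adjustment is
applied by default, matching the reporting convention; a Benjamini-Hochberg
column is available on request. Two constant samples compare as p = 1
(equal means) or p = 0 (different means) by convention. The
origin-constrained fit reports $R^2$ about the mean of y (a constant y
then yields $R^2 \le 0$, flagging a poor fit); the uncentered variant is
an option. The fit is unweighted by default because it is applied to
ensemble-average values; 1/sem² weights are available.

## Numerical summary of the sizes used

The shipped tests and the acceptance script run, on one CPU: a 240-node
closed ring down to half its radius (~1 s); a 181-node strip over 6 h
(~2 s); the 10-animal reference study (~10 s); 19 fiber images at
128×128 px; 40-slice z-stacks at 40×40 px; and 1000-case statistical
batteries. These sizes were chosen so the whole suite completes in about a
minute while every tolerance is still limited by method error, not by
sample size.

## Known limitations

* The triplet curvature estimator is noisy at landmark-scale sampling
  (sagitta of a 45 µm chord on a 300 µm circle is only ~0.8 µm); the
  pipeline relies on temporal smoothing and ensemble averaging exactly as
  the measurement convention prescribes.
* The pinned-strip simulator cannot represent the un-pinned tissue beyond
  the tracked region; conclusions near the strip ends are artifacts and
  are excluded by the margin, not corrected.
* `flattened_lateral` is defined here as a tangent-line continuation of
  the outer left flank (flattened length `2 * flatHalfWidth`), mirroring
  the medial construction; the original geometry is described only
  qualitatively.
* Recoil traces are inputs; no ablation-movie tracking is performed, and
  tensions are never absolute.
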