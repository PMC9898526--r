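# foldflow

Quantitative analysis of epithelial fold deepening in transverse
(medial-lateral × depth) sections, built around the Laplace-force law

&nbsp;&nbsp;&nbsp;&nbsp; **κ T − μ vₙ = 0**,

i.e. the local normal deepening speed of a fold front is proportional to
the product of its local curvature κ and the in-plane tissue tension T,
with μ a dissipative prefactor. The package is for developmental
biophysicists who track invaginating fold fronts over time, estimate
tension from laser-ablation recoil, and want to test the curvature-tension
law on their data — or on synthetic data with known ground truth.

It provides, as composable functions around S4 data classes
(`FoldFront`, `FrontSeries`, `CurvatureSpeedProfile`, `TensionProxyCurve`,
`CollapseDataset`, `OriginFit`):

* **Front geometry** — uniform arc-length resampling, circumcircle
  curvature on 22.5 µm triplets, normal deepening speed between frames,
  tissue thickness, material tracking toward a convergence center, neck
  depth (`localCurvature`, `normalSpeed`, `trackTowardCenter`, `neckDepth`).
* **Registration** — landmark-based Position_ML/AP normalization (midline
  0%, macrochaetae ±100%, per-side scales), tilt correction, temporal
  anchoring (last microchaete division = 22 hAPF, 1.27 rescaling of 29 °C
  data).
* **Recoil analysis** — initial recoil velocity as the 1–7 s regression
  slope of ablation displacement traces, 2 h sliding tension-proxy curves,
  the 0.00015 µm⁻¹ curvature-threshold dataset rule, apical-basal
  correlation.
* **The model** — a stable forward simulator of vₙ = κT/μ for open pinned
  strips and closed rings (`simulateFlow`), the collapse of speed against
  κ·T with origin-constrained fitting and the exact error-propagation
  formula σ_κv = κ̄σ_v + v̄σ_κ + σ_vσ_κ (`buildCollapse`,
  `fitThroughOrigin`, `recoverMu`, `productError`), and curvature
  homogenization diagnostics (`homogeneityCV`).
* **Image operators** — apical-surface topographic maps from z-stacks and
  offset projections, F-actin fiber skeletonization with length-weighted
  orientation statistics, curvature-binned intensity profiles
  (`apicalZMap`, `projectOffset`, `segmentFibers`, `intensityVsCurvature`).
* **Synthetic data** — generators for multi-animal fold-front ensembles
  evolving under the flow with configurable geometry, tension schedule,
  landmark noise and seeds, plus recoil traces, fiber images and z-stacks
  with ground truth (`studyConfig`, `simulateEnsemble`, `synthRecoilTrace`,
  `synthFiberImage`, `synthZStack`).
* **Reporting statistics** — Welch tests with the white/striped/plain
  p-value banding, per-timepoint condition comparisons, one-way ANOVA
  (`welchTest`, `pBand`, `compareTimecourses`, `anovaOneway`).

## Worked example

Simulate the reference study — ten animals sharing a medially flattened
front (radius 300 µm, flat half-width 100 µm) deepening under a tension
ramp with μ = 4 × 10⁻⁴, 0.5 µm landmark noise and 5% recoil-proxy noise —
then run the full measurement pipeline and recover μ from the collapse:

```r
library(foldflow)

cfg <- studyConfig(seed = 1)
res <- runPipeline(cfg)

res$profile
#> CurvatureSpeedProfile: 730 (time, position) cells, 1.9% filtered out

res$fit$fit
#> OriginFit: slope = 2539.89 +/- 14.1, R^2 = 0.9158 (n = 730)

res$fit$muHat
#> [1] 0.0003937176
```

The profile holds the ensemble mean curvature and deepening speed per
(time, Position_ML) after 1 h 45 min smoothing and the coverage /
curvature-sem filters. The origin fit of deepening speed against κ·T has
slope 1/μ̂: here μ̂ = 3.94 × 10⁻⁴, within 2% of the true 4 × 10⁻⁴, with
R² = 0.92 — the law holds on data the law generated, through the same
estimators one would apply to microscopy-derived fronts. A noise-free run
(`landmarkNoiseSd = 0, proxyNoiseCv = 0, landmarkSpacing = 5`) recovers μ
within 0.1%.

The methods vignette (`vignettes/foldflow-methods.Rmd`) documents the
model, every measurement convention, the integrator's stability bounds,
and what the synthetic study does and does not emulate.

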