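---
title: "Quantifying posterior-circulation stenosis and its link to cognitive impairment"
author: "stenoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying posterior-circulation stenosis and its link to cognitive impairment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoscore)
```

## The problem

Narrowing of the posterior circulatory arteries — the basilar artery (BA)
and the paired posterior cerebral arteries (PCA) — reduces blood supply to
the hippocampus, thalamus and posterior cortex, territories central to
memory and executive function. Time-of-flight MR angiography (TOF-MRA)
shows flowing blood as bright tubes on a dark background without contrast
agent, so the degree of focal narrowing can in principle be measured
automatically and treated as a continuous risk marker, alongside the
blood-pressure profile, for cognitive impairment (CI) in the elderly.

`stenoscore` implements that whole chain: a geometric vessel-quantification
pipeline producing a per-artery stenosis score from a 3D volume, the
epidemiological layer (BP feature derivation, nested case-control matching,
logistic odds ratios, rank-correlation screens), and a four-learner
cross-validated risk-prediction layer with DeLong ROC comparisons. Because
no suitable imaging or cohort data are publicly deposited, the package also
ships first-class synthetic generators — vessel phantoms with analytic
ground truth and cohort simulators with known effect sizes — so every stage
is testable end to end.

## The stenosis score

For one artery, let $d(s)$ be the lumen diameter at arclength $s$. The
maximum-narrowing index is

$$ S = \left(1 - \frac{d_{\min}}{d_{\mathrm{average}}}\right) \times 100\% $$

with $d_{\min}$ the minimum and $d_{\mathrm{average}}$ the mean diameter
over the analyzed artery. $S$ lies in $[0, 100)$ — zero for a perfectly
uniform vessel — and is dichotomized into $<50\%$ and $\ge 50\%$ grades,
with $S = 50$ in the upper grade. The mean is taken over the *entire
retained profile* of the extracted artery (the literal reading of
"average diameter of the artery analyzed"); a windowed local reference is
available via configuration but is not the default.

## The imaging pipeline

`score_posterior_circulation()` composes seven stages; every parameter
below is in `pipeline_config()` and every run writes the resolved values,
plus a configuration hash, into its provenance record.

1. **Isotropic resampling** (`resample_isotropic()`). Clinical TOF-MRA is
   anisotropic (e.g. 0.57 mm in-plane with 1.4 mm slices); trilinear
   resampling to an isotropic grid restores comparable resolution in all
   directions. The default target of 0.5 mm was chosen by a phantom
   convergence study: it is slightly finer than the typical in-plane
   resolution, so the later threshold recovers the vessel wall with
   subvoxel precision from the partial-volume intensity ramp, which
   matters most at deep stenoses whose throat is under two voxels wide.
2. **Segmentation** (`segment_vessels()`). A global threshold — by default
   the Otsu bimodal split, with the plateau of equally optimal cuts
   resolved to its middle so well-separated classes are bisected —
   followed by removal of components below a physical size floor
   (2 mm³) and marker-based watershed on the interior Euclidean distance
   transform (markers: distance-transform local maxima at a 3 mm minimum
   separation) to split touching structures into instances.
3. **Skeletonization** (`skeletonize_mask()`). Topology-preserving
   sequential thinning: only simple points are removed (one 26-connected
   object component in the punctured neighborhood, one 6-connected
   background component in the 18-neighborhood), in increasing order of
   the distance transform so the surviving curve sits on the medial axis;
   curve endpoints are preserved. Spurs shorter than 3 mm hanging off a
   junction are pruned at the graph level, with a re-thinning pass to
   clear redundant attachment voxels.
4. **Topology graph** (`build_centerline_graph()`). Skeleton voxels with
   one 26-neighbour are endpoints, with three or more are junctions
   (adjacent junction voxels collapse into one node); voxel chains
   between nodes become edges with physical lengths. Cycles are allowed
   (the circle of Willis is a cycle); self-loops are collapsed.
5. **Artery extraction** (`extract_target_artery()`). Each edge is scored
   against an anatomical prior — seed-point proximity
   ($e^{-d/10\,\mathrm{mm}}$, weight 0.4), orientation agreement
   (weight 0.4), length adequacy (weight 0.2) — after a hard orientation
   gate (cosine ≥ 0.45): a chain 60-some degrees off the expected course
   is never the target, whatever its other terms. Laterality uses the
   radiological display convention (subject-left on image-right),
   configurable; mirroring a volume therefore swaps the left/right PCA
   labels, which is itself one of the tests.
6. **Straightening and diameter profiling** (`straighten_artery()`). The
   centerline is resampled at 0.5 mm arclength steps and smoothed with a
   1 mm Gaussian; cross-section planes orthogonal to the tangent are
   carried along by parallel transport (the rotation + translation of
   sections into a common frame). The lumen cross-section is the
   4-connected in-plane region containing the centerline point, sampled
   at half-voxel resolution on a half-step-shifted grid (so samples never
   sit exactly on voxel boundaries, where round-half-even would bias the
   area); the diameter is the equivalent-circle value
   $2\sqrt{A/\pi}$, chosen over a minimum-caliper width for noise
   robustness. Sections within 2 mm of either terminus are excluded; a
   terminus at a junction is additionally trimmed by the local junction
   radius (from the distance transform), because planes inside the
   bifurcation blob unavoidably cut the sibling artery's lumen. Empty
   sections are dropped with a warning; more than 20% dropped is an
   error.
7. **Scoring** (`compute_stenosis_score()`): the ratio formula above,
   requiring at least three retained sections.

One artery may fail while the others succeed; the report then carries the
error message in that artery's slot.

## The phantom generator

`generate_phantom()` builds volumes with known truth. An artery is a
natural cubic spline through control points carrying the radius profile

$$ r(s) = r_0 \left(1 - \textstyle\sum_k \delta_k \,
   e^{-(s - p_k)^2 / 2 w_k^2}\right), $$

a Gaussian dip per stenosis with depth fraction $\delta_k < 1$ (the lumen
never fully occludes), center $p_k$ and width $w_k$ (mm). Nothing pins down a
canonical lesion geometry; the Gaussian dip was chosen
as the simplest smooth shape that is parameterized by depth and width and
integrable to an analytic truth. The true score is computed on a fixed
4097-point arclength grid of the continuous radius function, so it is
exactly invariant to voxel spacing and noise settings. A voxel belongs to
the lumen iff its center lies within the interpolated radius of the
nearest point of the densely resampled centerline; distances are taken to
the polyline *segments*, since nearest-sample distances systematically
exceed the true curve distance and at degenerate radius/spacing ratios
(3 mm at 0.6 mm spacing) that bias excludes an entire lattice ring of
exact-boundary voxels, depressing the base diameter by ~8%.

Voxels cut by the wall receive the partial-volume mixture
$\mathrm{bg} + (\mathrm{fg} - \mathrm{bg}) \cdot f$, where $f$ ramps
linearly in the signed wall distance over one mean voxel width. This
emulates the finite point-spread of MR acquisition — real edge voxels are
intensity mixtures, never knife-edged — and it is what makes deep
stenoses recoverable at all: with a binary phantom the subvoxel position
of a 1.2 mm throat is simply not encoded in the data. What the phantom
deliberately does *not* emulate: flow-related signal loss and saturation,
coil inhomogeneity, ghosting, and anatomically faithful circle-of-Willis
variants. Passing the recovery grid therefore demonstrates geometric
correctness of the measurement chain, not robustness to MR physics
artifacts.

The named fixture `posterior_circulation_spec()` is one BA trunk
bifurcating into two PCA branches — 1 junction, 3 endpoints — which fixes
the topology oracle. The default acquisition geometry is a 0.6 mm
isotropic grid: the generator requires `base_radius >= 2 * max(spacing)`
for resolvability, and 0.6 mm accommodates the 2 mm phantom-grid radius
as well as a PCA radius of 1.6 mm.

## The cohort simulator

`generate_cohort()` draws an elderly, mostly male cohort (age
$\mathcal{N}(84.5, 6.5^2)$ truncated at 65, 89.4% male, BMI
$\mathcal{N}(24.3, 3.2^2)$) with repeated supine BP/pulse measurements
(between-subject SBP $\mathcal{N}(131, 9^2)$, DBP $\mathcal{N}(70, 6^2)$,
within-subject noise 8/5/4 mmHg or bpm, a heavy-tailed negative-binomial
measurement count, and an enforced SBP − DBP ≥ 10 mmHg floor), gamma
stenosis scores (BA shape 8 scale 2.2; PCA shape 2.2 scale 14, capped at
95), and vascular history flags at literature-typical prevalences. The
binary CI outcome follows

$$ \mathrm{logit}\, P(\mathrm{CI}) = \beta_0 + \beta_{PP}\,\mathrm{PP} +
   \beta_{L}\,\mathrm{LPCA} + \beta_D D + \beta_M M + \beta_S S $$

in the subject's *true* (noise-free) features, with defaults
$\beta_{PP} = \ln 1.04$ per mmHg, $\beta_L = \ln 1.021$ per percent, and
positive history effects — the effect directions the association layer is
expected to recover. The intercept default (−3.96) centers prevalence
near 0.35 at the feature means. All draws are seeded and bit-reproducible.

## Statistical conventions

- **Derived pressures.** Measurements are averaged first; then
  PP = SBP − DBP, MAP = DBP + PP/3, PPI = PP/SBP from the means. For PP
  and MAP the order is immaterial (linearity); for PPI it is not, and the
  means-first order is the documented choice.
- **Categories.** Three levels per parameter with `[lower, upper)`
  intervals, top interval closed above by infinity: SBP 120/135, DBP
  70/80 (guideline stages), PP 58/66, MAP 88/93, PPI 0.45/0.49, pulse
  68/72 (published cohort tertiles, shipped as the `"guideline"` preset);
  empirical tertiles are available instead. The middle level is the
  modelling reference.
- **Matching.** 1:1, sex exact, age within ±1 year; greedy nearest-age in
  seeded random case order, ties broken to the smallest control id, each
  control used once, unmatched cases reported rather than fatal. The
  matcher in the source study is undocumented; this deterministic greedy
  scheme is the package's choice.
- **Group comparisons.** Continuous variables go to the t test when both
  groups pass Shapiro-Wilk at α = 0.05, else Mann-Whitney; categorical to
  chi-squared, with Fisher fallback (warning) when an expected count
  drops below 5. The normality gate is a documented choice; the source
  names both tests but not the rule.
- **Odds ratios.** Maximum-likelihood logistic fits; Wald 95% intervals
  on the log-odds scale (the usual reporting style when no method is
  named). Complete cases per model. Separation is detected (huge
  coefficient with huge standard error) and reported as an error naming
  the predictor, never silently returned.
- **Prediction.** The "8:2 split" and "5-fold cross-validation" are
  combined as: stratified 80/20 split; 5-fold CV *inside* the 80% for
  model assessment; a single final evaluation on the 20%. Both CV and
  holdout AUCs are reported. Hyperparameters (unpenalized LR; tree depth
  4; 500 trees; radial SVM at cost 1) live in `learner_config()`.
  Features are standardized with statistics fit on each training part
  only; constant features are dropped with a warning. SVM scores are the
  decision values mapped monotonically through the logistic function,
  oriented by the model's own class ordering — AUC is invariant to any
  monotone map, which is also a test.
- **DeLong.** Implemented directly via placement values so the degenerate
  self-comparison returns exactly p = 1; cross-checked against
  `pROC::roc.test` to 1e-9 in the suite. The AUC itself is the
  Mann-Whitney statistic (ties counted half), identical to the
  trapezoidal ROC area.

## Problem sizes

The shipped analyses and tests use: a 3×3×3 phantom grid (radius 2/3/4 mm,
depth 0.2/0.45/0.7, noise 0/5/10% of contrast) with 3 seeds per cell (81
pipeline runs, about 7 s total); 200 cohort replicates at n = 5000 for the
Wald-coverage study; n = 2000 cohorts for the association and prediction
layers; and 20 seeded replicates for the feature-set-3 vs feature-set-1
comparison. These sizes give stable Monte-Carlo estimates (binomial SE
≈ 1.5 points for the coverage study) while keeping a full run in the low
minutes on one core.

## Known limitations

- Thinning erodes roughly one radius from each open vessel end before a
  curve endpoint forms, so profiles do not reach the anatomical termini;
  the end-trim absorbs this.
- The segment-based rasterization is exact for straight tubes and
  convergent elsewhere; strongly curved vessels with radius comparable to
  the curvature radius would violate the tube model itself.
- The watershed instance labels are recorded but the diameter profile is
  taken from the binary mask; vessels touching wall-to-wall over long
  stretches (not present in the posterior-circulation geometry) would
  require instance-aware profiling.
- Logistic odds ratios are non-collapsible: the cohort generator's
  marginal single-predictor fits match their generating coefficients only
  when the remaining coefficients are zero, which is how the calibration
  study is configured.
- The risk-prediction AUCs on synthetic cohorts reflect the generator's
  signal-to-noise choice, not any clinical performance claim.
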