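---
title: "Scenario-targeted synthetic human scenes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scenario-targeted synthetic human scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthretarget)
```

## The problem

Detecting people in hospital wards is hard for off-the-shelf detectors:
patients lie supine under blankets, cameras sit at oblique, rolled,
sometimes near-floor angles, and privacy rules make it nearly impossible to
collect the annotated video such models would need for fine-tuning. The
package implements *synthetic retargeting*: procedurally generating
scenario-tailored synthetic images of humans in bed-centric scenes — with
exact ground-truth boxes, 17-keypoint skeletons and 3D joints — so a
pre-trained detector can be adapted to one specific deployment viewpoint
without touching real patient data. It also implements the evaluation and
statistics machinery needed to quantify whether such retargeting helped.

This vignette records the models the package implements, the parameters
that matter, and the design decisions taken where the procedure was
genuinely open.

## The articulated humanoid

The body is a kinematic tree of 27 joints: a 22-joint SMPL-compatible body
subset plus five face joints (nose, eyes, ears), so that all 17 COCO person
keypoints are tree joints with no interpolation. The tree ships as a
plain-text asset (`inst/extdata/kinematic_tree.txt`) giving, per joint, its
parent, its rest offset in metres, and a per-axis pose limit in radians used
by the pose generator. The rest pose is supine: head toward +x, anatomical
left toward +y, +z up, pelvis at the origin — a deliberate bed-centric
convention so that "above the bed" is simply +z.

Poses are per-joint axis-angle vectors (direction = axis, norm = angle,
norms kept in $[0, \pi]$). `forward_kinematics()` composes rotations down
the tree; `pose_from_joint_positions()` inverts it from Cartesian joint
positions, which is the representation motion-capture sources provide.
Two details are worth recording:

* **Twist is unobservable.** A bone's rotation about its own axis does not
  move any joint. Single-child joints therefore get the *minimal* rotation
  mapping the rest bone direction onto the observed one (twist = 0); joints
  with several children (pelvis, chest, head) get the least-squares rotation
  over all child directions (Kabsch via SVD), which is exact on
  kinematically consistent input. The composition
  `forward_kinematics(pose_from_joint_positions(x))` reproduces joint
  positions to better than 1e-6 m on random joint-limited poses — a
  position-level identity, not a rotation-level one.
* **Translation is excluded.** The root translation is carried separately,
  so the rotational pose of a translated skeleton is identical to the
  untranslated one. This is what makes poses transferable across body
  shapes.

Body shape is 10 dimensionless coefficients (betas) drawn from
Normal(0, sigma) and constrained to $[-1, 1]$. The draw is by *rejection*,
not clipping: clipping would pile probability mass onto the boundary values,
which no real shape distribution has. The spread sigma defaults to 0.5 —
the distribution's mean (0) and support ($[-1,1]$) are fixed by the sampling
scheme; the spread is not, so it is exposed as a parameter. The first beta
scales stature (factor $1 + 0.1\beta_1$), the mean beta scales segment girth
(factor $1 + 0.15\bar\beta$), making total mesh volume strictly monotone in
the betas.

The surface itself is procedural: one capped-cylinder capsule per bone plus
a head ellipsoid, with per-face body-part labels used for clothing overlays
and blanket-region logic. This stands in for a learned statistical body
surface behind the same `(joints, shape) -> mesh` interface; an adapter
supplying externally produced meshes can replace it without touching any
downstream code. Tessellation (8 ring segments, 3 lengthwise) is even-count
so the rest-pose mesh is exactly mirror-symmetric about the sagittal plane.

## Scene sampling

Each scene draws, in order: shape, pose, appearance, blanket, camera; each
of its renders re-draws lighting and the background reference. What varies
across the four renders of one configuration was an open point — the source
procedure says only that one mesh "was rendered under varied lighting
conditions" — and holding pose/shape/camera fixed while varying lights and
background both matches that phrasing and lets annotations be reused across
renders.

**Appearance.** Skin colour is a uniform draw from an RGB skin-tone palette
(8 tones shipped, configurable); clothing, hair and eyewear are independent
toggles (defaults 0.5 / 0.5 / 0.3). Clothing is a flat-colour overlay on the
torso, pelvis, thighs and upper arms; constructing deformed garment meshes
was left out deliberately, since no reproducible procedure for it exists —
the occlusion realism burden is carried by the blanket instead.

**Blanket.** The occluder is a heightfield drape: a planar grid over part of
the body's footprint takes, per cell, the maximum body-surface height
underneath, is tented by a one-cell morphological dilation (cloth cannot
drop vertically at a silhouette edge — this also guarantees smoothing never
pulls the sheet inside the body), offset by `offset` (default 3 cm), jittered
with i.i.d. Gaussian noise (default 8 mm), and smoothed. Smoothing uses the
operator $h \leftarrow h - (\lambda/4) L h$ with $L$ the symmetric
4-neighbour grid Laplacian and $\lambda = 0.5$; its spectrum lies in
$[0, 1]$, so height variance is provably non-increasing per iteration and
the mean height is preserved. Coverage fraction is drawn from
$U(0.3, 0.9)$ of body length with a uniform anchor; 70% of scenes get a
blanket by default.

**Camera.** The camera sits on a sphere about the pelvis at distance
$d \in U(0.3, 0.6)$ scene units, azimuth drawn from the scenario preset,
elevation from $U(-54°, 18°)$, and is rolled about its optical axis by
$U(-115°, -30°)$ — the roll interval is asymmetric as printed in the source
ranges, attributed there to the mismatch between the pelvis-anchored body
frame and the renderer's world frame, and is adopted verbatim. Two
conventions had to be fixed because the original renderer's axes are
undocumented:

* *Elevation sign*: positive = camera above the horizontal plane through the
  pelvis; a preset-level `flip_elevation` switch exists because the opposite
  reading cannot be excluded.
* *Scene units*: the distance range has no stated unit. It is interpreted as
  `distance * unit_scale` metres with `unit_scale = 5` (so 1.5–3 m), chosen
  once so that, with the default focal length (0.8 × image width), the body
  fills roughly 40–90% of the frame height across the distance range.

Scenario presets bundle the azimuth ranges: **B** spans −35° to 35° about
the bed's *right side*, **C** 15° to 35° about the bed's *front*, and **D**
views the bed front dead on — implemented as the degenerate interval
$[0°, 0°]$ rather than a special case, so D flows through the same sampler.
All presets default to 2,700 configurations × 4 renders = 10,800 images.

**Lights.** Five directional lights — front, back, left, right, above —
each aimed at the mesh, intensities i.i.d. $U(0.3, 3.0)$.

## Rendering and ground truth

The built-in renderer is a z-buffered software rasterizer (Rcpp) with
per-face flat Lambertian shading summed over the five lights; depth is
interpolated perspective-correctly via $1/z$. It makes no attempt at
photorealism — no shadows, textures or anti-aliasing — because its contract
is *annotation exactness*: alpha is nonzero exactly where geometry projects,
the bounding box is the tight box of opaque pixels, keypoint visibility
follows the COCO convention (0 outside the frame, 1 present-but-occluded
resolved against the z-buffer with a 0.15 m slack for the joint sitting one
limb radius under the surface, 2 visible), and 3D joints are reported in the
camera frame. The interface is renderer-agnostic: any backend mapping
`(scene config, meshes) -> annotated RGBA layer` can be slotted in, and a
photoreal engine would change pixels, not annotations. Shading is two-sided
and linear in the light intensities at `ambient = 0` (the default adds a
small 0.15 ambient term purely for legibility).

Pixel conventions (origin top-left, y down, 0-based, sample points at pixel
centres, inclusive edge coverage, `[x, y, w, h]` half-open boxes) are fixed
in one place and property-tested against an analytic half-plane oracle.

## Compositing and augmentation

Rendered layers are alpha-composited into backgrounds "near or on the bed".
The source gives no numbers for *near*, so it is quantified as: uniform
scale such that the human's long axis is $U(0.6, 0.95)$ of the bed box's
long axis, translation re-sampled until the placed human box overlaps the
bed box (dilated by 20%) by at least 0.3 of its own area, bounded retries,
then failure with diagnostics. Keypoints and boxes ride through the same
similarity transform, so replaying the stored provenance transform
reproduces layer keypoints exactly. Bed regions come from one-line JSON
sidecars (or the procedural background generator, which records its bed box
exactly); a pluggable detector hook exists but no model ships, keeping the
package download-free.

The rotation augmentation used to make upright datasets resemble lying-down
scenes draws angles uniformly from $[70°, 110°] \cup [-110°, -70°]$ with
equal mass per interval, rotates the image about its centre onto an expanded
canvas (exposed pixels black — expansion rather than cropping, so no
annotation is ever lost), and recomputes boxes as the tight box of the
rotated corner points. Rotating an upright (taller-than-wide) box by any
angle in these intervals provably flips the sign of $\ln(w/h)$.

## Evaluation

The evaluation chain is the standard detection stack with the canonical
thresholds: confidence filtering at 0.001 (0.2 for the pose pipeline),
greedy NMS at IoU 0.65, and AP/AR averaged over IoU thresholds 0.50–0.95 in
steps of 0.05 (101-point interpolated AP, max-recall AR, single category,
up to 100 detections per image). OKS uses the standard 17 per-keypoint
constants with $\mathrm{OKS} = \sum_i e^{-d_i^2 / (2 s^2 k_i^2)}
[v_i > 0] / \sum_i [v_i > 0]$, $s^2$ the ground-truth area.

The per-person score is the quantity the statistics run on: each
ground-truth person is matched one-to-one to detections (globally greedy by
IoU, ties to higher confidence then lower ground-truth id) and scores the
matched IoU *only when it reaches 0.75*, else 0. The defining source line is
truncated mid-formula, so this reading — continuous IoU above the threshold,
which simultaneously rewards detection and localisation — was adopted; a
binary 1/0 variant ships behind `eval_config(score_mode = "binary")`. The
0.75 rule makes scores strongly non-normal (a point mass at 0), which is
exactly why the Wilcoxon test is the primary criterion below.

## Statistics

Paired per-person score vectors are compared with three tools: the paired
t-test (supplementary), the Wilcoxon signed-rank test (primary, because of
the non-normality above), and a percentile bootstrap CI on the mean
improvement (reported in percentage points, i.e. 100 × the mean score
difference). Implementation decisions:

* Wilcoxon zeros are dropped (classic handling rather than the Pratt
  variant); a flag marks comparisons where more than 10% of pairs were
  zero. With all differences zero the test is undefined and reported
  degenerate with p = 1.
* For n ≤ 25 the two-sided p comes from the *exact* null distribution of
  the signed-rank sum, enumerated by dynamic programming over doubled
  midranks (so ties are handled exactly); above that, the normal
  approximation with tie correction and continuity correction.
* The bootstrap is percentile with 10,000 replicates by default (BCa is
  available behind a flag); percentile is the simplest defensible reading
  of an unspecified "bootstrap CI".

The comparison family is all unordered dataset pairs within each scenario —
{pretrained, A, B, D} in scenario 1 (6 pairs), {pretrained, C, D} in
scenario 2 (3 pairs) — crossed with 5 architectures: 45 tests. Bonferroni
control divides the familywise 0.05 by 45, and the per-test level is
reported rounded to 4 decimals (0.0011) alongside the exact value, matching
how such thresholds are conventionally quoted.

```{r grid}
bonferroni_alpha(0.05, comparison_grid())[c("exact", "rounded", "n_tests")]
```

## Dataset bookkeeping and diagnostics

COCO JSON is written canonically (fixed key order, coordinates rounded to
1e-6 px), so a fixed dataset is byte-stable — the determinism contract is
byte-identical manifests, annotation files and rasters for identical seeds.
3D joints live under a namespaced `x_joints3d` key so files remain valid
standard COCO. The train/validation split (10,000 / 800 at full scale) is
uniform without replacement but *grouped by configuration*: the four renders
of one configuration differ only in lighting and background, and letting
them span the split would leak near-duplicates into validation. This is
stricter than the source states, which does not say whether its 800-image
validation set grouped renders; grouping is the safe reading.

Targeting quality is diagnosed through each box's $\ln(\text{width} /
\text{height})$: lying-down boxes are wide (positive), upright ones tall
(negative). Two datasets are compared by Jensen–Shannon divergence between
histograms on 50 shared bins (symmetric, bounded by $\ln 2$ nats, zero only
for identical histograms) — a scalar stand-in for what the source assesses
visually; the source's density estimator is unstated, and shared-bin
histograms make the "rank candidate datasets by closeness to the target"
operation deterministic.

## What the synthetic generator does and does not emulate

The fixtures module stands in for every external asset: procedural ward
backgrounds (wall/floor bands, a bed with frame and pillow, distractor
rectangles, bed box recorded exactly) replace harvested indoor photographs;
a reflected random walk within per-joint limits, started from the supine
rest pose, replaces motion-capture pose archives; and `perturb_to_target_iou()`
manufactures detections at a chosen IoU (bisection on shift magnitude,
±0.01) for exercising the scoring boundary. These reproduce the *geometry*
and *bookkeeping* of the real pipeline — viewpoint distributions, occlusion
statistics, annotation exactness — but not photometric realism, garment
deformation, motion dynamics, or the texture statistics of real wards.
Passing tests therefore certify the machinery (sampling ranges, annotation
exactness, metric and statistical correctness), not that a detector
fine-tuned on these rasters would transfer to real video; that transfer
claim requires trained detectors and clinical footage, which are explicitly
out of scope.

## Numerical choices and degenerate inputs

* Seeds: one master seed fans out through `derive_seed(seed, key)` (a
  congruential mix, all arithmetic below 2^53) so subsystems draw from
  independent streams and adding draws to one stage never perturbs another.
* Rasterizer ties: equal-depth fragments go to the earlier face; pixel
  centres exactly on shared edges are covered by both faces, depth deciding.
* `ap_ar()` with no ground truths returns NA (undefined), not 0; an empty
  detection set gives AP = AR = 0.
* Two empty boxes have IoU 0 by convention; degenerate (zero-length) bones
  abort pose conversion naming the joint.
* Bisection for IoU targeting runs 60 iterations, far past the ±0.01
  acceptance band.

## Problem sizes used by the test-suite

The suites exercise full-scale *bookkeeping* (the 10,800-image plan and its
10,000/800 split are built and split exactly, without rasterising) and
moderate-scale *rendering* (a 200-image fully rasterised run at 320 × 240;
individual render tests at 160 × 120). Statistical calibration uses 2,000
null simulations for type-I error, 2,000 simulations (400 bootstrap
replicates each, n = 200) for CI coverage, and full 2^n enumeration up to
n = 10 for Wilcoxon exactness. Oracle-equivalence checks run 100 randomised
instances each for AP/AR and IoU and compare bit-for-bit against brute-force
reimplementations. These sizes were chosen as the smallest at which each
property is sharply testable.

## Known limitations

* The capsule body is coarse: no hands, feet are single segments, and the
  silhouette underestimates clothing bulk. Downstream consumers wanting
  realism should plug a real body-model backend into the adapter seam.
* Flat shading with five lights cannot produce cast shadows or
  inter-reflections; the domain gap of the built-in renderer is therefore
  larger than that of a game-engine backend.
* The blanket is a heightfield: it cannot hang over the bed's vertical
  sides or fold.
* `score_persons()` matching is globally greedy, not optimal assignment;
  tests verify it coincides with the optimal total on instances without
  threshold-straddling ties, and ambiguity beyond that is inherited from
  the method being modelled.
* The normal-approximation branch of the Wilcoxon test is conservative for
  n just above 25 with heavy ties.
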