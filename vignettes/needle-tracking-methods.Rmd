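---
title: "Markerless needle tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless needle tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needletrack)
```

## The problem

During percutaneous needle biopsy the operator must drive a needle along a
pre-planned straight trajectory from a skin entry point to a target lesion.
A mixed-reality headset can overlay the planned trajectory and the
patient's reconstructed anatomy directly on the body, but that requires
tracking the needle itself - without gluing markers to the tool. This
package implements such a markerless tracking pipeline, plus the
registration and guidance machinery around it, against a synthetic scene
generator that stands in for headset hardware.

The tool is modelled as a rigid assembly: a *grabber* (handle, here a
cylinder 80 mm long, 12 mm diameter) coaxial with the needle (120 mm or
160 mm long). Two sensors observe it: an RGB ("PV") camera, in which the
thin needle is visible, and a near-range depth camera, which returns
points on the grabber only - a thin polished needle yields no usable depth
returns. The pose estimation problem is therefore split: find the needle
*line* in the image, find the grabber *axis* in 3D, and extrapolate the
tip a known needle length along the axis.

## Pipeline stages

1. **Tool segmentation** (`segment_tool`). The reference segmenter is
   deterministic: Otsu threshold, morphological opening (which removes the
   thin needle), largest connected component. It is a plug-in point - any
   mask provider with the same signature (for instance a trained instance
   segmentation network) can replace it; everything downstream only needs
   a logical mask.
2. **Edge detection** (`detect_edges`). Canny-style: Gaussian smoothing
   (sigma = 1 px), Sobel gradients, non-maximum suppression along the
   gradient, dual-threshold hysteresis with 8-connectivity.
3. **Threshold tuning** (`tune_edge_thresholds`). The hysteresis
   thresholds are tuned per scene by a Grey Wolf Optimizer. No canonical
   fitness exists for this step, so the package defines one: maximise the
   fraction of edge pixels inside the tool mask dilated by 5 px, minus a
   mild penalty `0.1 * |E - A| / A` (E = edge count, A = mask perimeter
   estimate). The first term concentrates edges on the tool; the second
   rejects the degenerate all-edges and no-edges optima. The GWO is the
   canonical continuous variant (alpha/beta/delta leaders, exploration
   parameter decaying linearly 2 to 0, positions clamped to bounds) with an
   explicit seed; defaults are 20 wolves and 30 iterations, and the tuner
   minimises by default (`maximize = TRUE` flips the sign internally).
4. **Hough transform** (`hough_lines`). Normal parameterisation
   `u cos(theta) + v sin(theta) = r`. **Note the convention**: `theta` is
   the angle of the line's *normal*, not of the line itself - the voting
   equation only holds under the normal convention. `theta` spans [0, pi)
   with signed `r`, which resolves the (r, theta)/(-r, theta + pi)
   ambiguity. Defaults: 1 px rho resolution, 1 degree theta resolution,
   vote threshold 20 (a line must collect more than 20 collinear edge
   pixels).
5. **Line selection** (`select_needle_line`). Among candidate lines the
   winner maximises `mask_overlap - 0.5 * dtheta - 0.01 * dr`, where
   `mask_overlap` is the fraction of the line's in-image pixels inside the
   dilated mask and `dtheta` (radians) / `dr` (pixels) measure distance to
   the previously tracked line (zero weight on the first frame). A
   multi-frame velocity model would also fit here; a single-previous-line
   prior proved sufficient at tracking rates of tens of Hz, where
   inter-frame motion is small.
6. **3D lift** (`gate_points`, `fit_line3d`, `estimate_tip`). Depth points
   are range-gated to the sensor's reliable near band (300-1000 mm),
   transformed to world coordinates by the inverted depth extrinsics,
   projected into the image, and gated to the selected line. The 3D fit is
   *orthogonal* (total) least squares via the principal axis of the
   scatter - rotation-invariant, unlike coordinate-wise regression, which
   matters because the cloud is nearly axial. The tip is
   `base + needle_length * direction`, with the base at the projection of
   the grabber centroid advanced by `base_offset` (half the grabber length
   when depth returns cover the grabber uniformly).
7. **Smoothing** (`track_sequence`). A 12-state constant-velocity Kalman
   filter on (base, direction) with white-acceleration process noise,
   followed by an exponential moving average. Neither the state vector nor
   the stage order is canonical; the package filters first and EMA-smooths
   the filter output (configurable via `ema_first`), renormalising the
   direction after every update rather than filtering on a rotation
   manifold - adequate at 20 Hz pose rates.
8. **Registration and guidance** (`register_markers`, `apply_chain`,
   `plan_trajectory`, `alignment_metrics`). Paired-point fiducial
   registration is the closed-form Umeyama similarity fit; patient
   superimposition uses `fix_scale = TRUE` so the scan keeps its real
   scale, while the device-to-model chain supports a free scale factor.
   The device-synchronisation transform C is accepted as input (JSON) or
   identity - how the workstation and headset applications synchronise
   clocks/anchors is outside this package's scope.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pixel_tol` | 4 | px | image-line gate; clinical scenes are cluttered, keep tight |
| `sim_pixel_tol()` | radius px + 8 | px | simulated scenes: gate must span the grabber silhouette |
| `vote_threshold` | 20 | votes | minimum collinear support for a line |
| `base_offset` | 40 | mm | grabber centroid to needle base (half grabber length) |
| `process_noise` | 0.5 | mm^2/frame^3 | constant-velocity model slack |
| `measurement_noise` | 4 | mm^2 | per-axis pose observation variance (~2 mm sd) |
| `alpha` | 0.3 | - | EMA weight of the newest pose |
| range gate | 300-1000 | mm | near-depth sensing band |
| guidance thresholds | 3 mm / 2 deg / 10 mm | - | ALIGNED / NEAR cutoffs, set at the scale of observed placement errors (<= 1 cm) |

## The synthetic scene

`simulate_frame` renders the grabber (bright, intensity 0.80) and needle
(thinner, 0.55) on a dark background (0.12) with anti-aliased edges and
additive Gaussian pixel noise, and samples depth returns on a regular
(axial x circumferential) grid over the **full** grabber cylinder surface
plus isotropic Gaussian noise (default sd 2 mm, emulating the heavy
distortion of real headset depth clouds). Defaults place a 160 mm needle
upright 400 mm from the headset - the working distance at which near-range
depth sensing behaves best.

Idealisations to keep in mind when interpreting green tests:

* **Full-surface depth sampling.** A real depth camera sees only the
  camera-facing half of the cylinder, which biases a naive axis fit
  radially by about 2R/pi. The simulator samples the full surface
  symmetrically, which is what makes exact zero-noise recovery possible.
  Handling one-sided clouds on a real tool needs a cylinder fit or a
  per-tool calibration, which is exactly why markerless tracking "requires
  an individual approach for particular tools".
* No occlusion, no background clutter, no specular highlights; the
  segmenter plug-in absorbs that complexity on real data.
* Depth noise is isotropic Gaussian; real near-depth distortion is
  structured (wiggle, edge fattening). Noise magnitudes are configurable.
* No tissue: the puncture-study generator models execution error
  (angular + translational) geometrically, not needle-tissue mechanics.

Ground truth (true pose, true image line, grabber footprint, clean cloud)
is carried with every frame, so every pipeline stage is testable in
isolation and end to end.

## Numerical choices

* **Outlier rule in `fit_line3d`.** Residuals of points on a cylinder
  *surface* cluster near the radius, not near zero, so the robust cut is
  applied to the *deviation from the median residual*
  (`|res - median| > 2.5 x 1.4826 x MAD`), with an absolute floor of
  1e-6 mm on the threshold so that machine-epsilon jitter on exact
  geometry never rejects points. Gross outliers 100 mm off axis are still
  rejected reliably.
* **Hough binning.** Votes go to the nearest rho bin center with ties to
  the lower bin; the fractional part is compared exactly (`q - floor(q) >
  0.5`) because adding 0.5 before `floor()` double-rounds at representable
  near-half values and then disagrees with a brute-force nearest-center
  count. The accumulator is validated against exactly such a brute-force
  oracle.
* **Direction sign.** A line fit has no intrinsic orientation. When the
  grabber centroid projects away from the fitted anchor the sign follows
  "away from the grabber"; in the pipeline (where the gated cloud *is* the
  grabber and the rule is degenerate) the sign comes from image intensity
  sampled along the line beyond both grabber ends - the needle side is
  bright, the rear side is background. This is threshold-free and works
  even when tuned edge thresholds suppress the weaker needle edges.
* **Degenerate inputs.** Empty masks fall back to default thresholds and
  are flagged; empty edge maps yield empty candidate lists and a
  no-detection error; collinear or coincident marker sets raise
  degenerate-geometry errors; missed detections become predict-only
  Kalman steps; a non-positive-definite covariance triggers one
  symmetrization retry before failing.
* **Extrinsics convention.** `R|t` maps world to camera everywhere;
  depth-to-world is the inverted extrinsics. The headset convention is not
  documented publicly; all code and tests are self-consistent under this
  choice, and the calibration JSON states it.
* **Units.** Millimetres for all 3D quantities, 0-based pixels with origin
  top-left. No lens distortion model (a documented non-goal).

## Study summaries

`summarize_study` reports the mean of the *per-exam rounded* time
reductions (53% on the recorded ten-exam table) as the headline number,
because that is how the recorded table's average row is computed; the
aggregate-total alternative `(sum_without - sum_with) / sum_without`
(≈55%) is reported alongside. "First attempt" means exactly one puncture.
Experience groups partition on the >3-years flag.

## Problem sizes

Simulated studies in the test-suite and acceptance script use 200 x 200 px
frames (400 x 400 px for the zero-noise exactness checks), 100-frame
sequences for noise-propagation statistics, 200-frame static sequences for
smoother variance, and 500 punctures per lesion depth - sizes chosen so
the whole suite runs in well under a minute per study while keeping
Monte-Carlo error far below the effect sizes being asserted.

## Known limitations

* No estimate of insertion depth once the needle enters the body; the
  pipeline tracks the visible part only.
* Single needle per scene; no multi-hypothesis data association.
* The segmentation stand-in assumes a bright tool on a darker background;
  on real imagery the plug-in interface expects a trained segmenter.
* Registration quality is reported as FRE; target registration error at
  points away from the fiducials is not estimated.
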