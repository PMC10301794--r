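---
title: "Methods: depth-camera electrode localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-camera electrode localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(electrodecam)
```

This vignette documents the models, parameters and numerical choices behind
the pipeline, the assumptions of the synthetic validation scenes, and the
known limitations. It states no empirical result beyond what the package's
test suite computes.

## The measurement model

A depth-sensing camera records, per view, a 16-bit depth raster (mm; 0
encodes "no valid depth") and a gamma-compressed RGB image, together with
the white-balance color-temperature setting `K_W` the color sensor used.
The torso is scanned in 12–15 overlapping portrait views over roughly 270
degrees. Electrodes are held by clips whose circular head is red epoxy with
a blue painted rim, forming a planar disk-plus-ring fiducial centered on
the electrode. The pipeline's job is to turn the per-view rasters into a
single labeled set of 3D electrode centers.

Three observations drive the design:

* **Color constancy is the fragile part.** Clinical rooms mix illuminants;
  shaded regions behave like very high color temperatures (beyond the
  physical sensor's white-balance range). Marker detection therefore runs
  on *chromaticity* (brightness-normalized color) after an offline
  virtual-camera correction with an extended temperature range.
* **Geometry is self-sufficient.** With an upright patient and a known
  scan direction, each view can be placed in a canonical patient frame
  from the depth data alone, leaving only a z-rotation and small shifts
  between consecutive views — which symmetric point-to-plane ICP resolves.
* **Markers are small and partially occluded.** Per-view marker pixels are
  pooled across all registered views before clustering and fitting, so a
  marker clipped in one view is completed by its neighbours.

## White balancing and color correction

The sensor maps its temperature setting to channel gains
`Γ_R = Γ_K`, `Γ_B = 1/Γ_K`, `Γ_K = sqrt(2 (K_W − K_min)/(K_max − K_min))`,
normalized so both gains are 1 at the center of the range. Gray pixels are
selected inside two ellipses around the neutral 5500 K gamut point; the
ellipse spreads are interpreted as standard deviations, so the membership
test divides by `σ²` (a config toggle `ellipse_sigma_squared = FALSE`
restores the literal unsquared form). The exposure band excludes pixels
whose linear intensity falls outside `(0.00155, 0.955)` of the maximum —
the sRGB-linearized images of the 8-bit limits 0.02 and 0.98.

The update scaler is `γ = sqrt((r̄ b̄_W)/(r̄_W b̄))`; the absolute
brightness cancels. Two quantities gate each update: the current squared
chromaticity error `E` of the mean gray estimate, and the predicted
post-update error `E*`. For `E*` the package applies the gain `γ` to red
and `1/γ` to blue and renormalizes the chromaticities — this makes `E*`
exactly the error achievable by the update, so accepted updates strictly
decrease `E`. (Scaling both channels by `γ` without renormalization is
available as `estar_mode = "printed"` for sensitivity checks.) An update
is applied only when `E > 1.758e-8` and `E − E* > 1e-15`; the scaler is
converted to a temperature through the inverse gain model and clamped to
the sensor range.

Offline, each stored texture is reduced to an equal-gain representation
(red divided by, blue multiplied by, the gain at its recorded temperature,
evaluated on the virtual 2000–9000 K range) and the same loop runs on a
virtual camera starting from the recorded setting. Iteration stops when
the update test fails, when consecutive temperatures differ by at most
1 K, or — after at least 20 jittering iterations whose consecutive
differences stay below 10 K — at the mean of the three smallest updates in
that window. The iteration cap is 200. Saturation handling: pixels
overexposed in the *input* pass through untouched; pixels that overflow
any channel after rescaling are set to (1, 1, 1); pixels with any channel
below 1e-8 are zeroed; everything is clipped to 1.

Because the offline loop starts at the *recorded* setting, it assumes the
online controller tracked the illuminant into the sensor range (possibly
clamped at its limits). Presenting it with a texture carrying a large
untracked cast leaves too few pixels inside the gray-selection ellipses
and the texture is returned unchanged with a warning — the correction
refines, it does not bootstrap.

## Exposure scoring

The exposure controller uses the skewness of the 256-bin gray-value
histogram of the patient-masked, properly exposed pixels:
`τ*_{n+1} = τ*_n − S·τ_Δ·N_τ·Γ_ex`, with the gain crossover reference
`τ** = clamp(τ_frame, τ_min, τ_max)` and `τ_frame = 100` ms. The
histogram is computed in the linear domain by a left-bisection search over
precomputed linearized bin boundaries (no per-pixel gamma compression),
and the skewness is the *standardized* third central moment about gray
value 128 — the standardized form bounds the step size, which keeps the
controller stable. Defaults: `τ_Δ = 1` ms (a typical hardware step),
`N_τ = 5`. When the second moment vanishes the skewness is defined as 0.
A histogram from a single constant gray patch makes the controller
bang-bang (the skewness jumps between ±1); real and synthetic scenes have
enough dynamic range that the step shrinks smoothly near the optimum.

## Depth segmentation

Smoothing weights combine a 5×5 spatial Gaussian (`σ = 1.5` px, a common
choice for edge detection preprocessing) with a per-neighbour gradient
attenuation `exp(−ΔD²/(2σ_g²))`, `σ_g = 8` mm, fetched from a precomputed
table indexed by the *squared* integer gradient via left bisection (no
square roots or exponentials per pixel). Undefined pixels are copied
unchanged and excluded from all sums.

Edges are zero crossings of an octagonal Laplacian (corner weights scaled
by `1/√2` so all eight neighbour distances are effectively equal; center
weight `4 + 2√2`). The step magnitude of a candidate is the maximum over
the four opposing-neighbour pairs, with one-sided differences doubled when
a neighbour is undefined. Primary edges exceed 12 mm; the minor-edge rule
`(ΔD > 3.5) ∧ ((ΔD > 12) ∨ ((ΔD − 3.5)/(12 − ΔD) > 1))` admits the
remaining candidates. The patient is the largest 4-connected component of
defined, non-edge pixels in the central segment of a 3×3 split that
touches the segment boundary (ties broken toward the image center),
extended by flood fill from its center of mass. The per-row depth band
keeps pixels with `D_close ≤ D ≤ D_far`; the comparisons are inclusive so
a perfectly flat synthetic foreground (all row minima equal to the maxima)
is not annihilated — with measured data the two forms are
indistinguishable. Components below 200 px, or without a valid band, are
skipped in favour of the next largest; a frame with no valid component is
skipped entirely.

## Meshing

Masked pixels are backprojected through the depth intrinsics onto a
pre-triangulated grid; every quad splits along the same top-left to
bottom-right diagonal with a winding that faces the depth camera. Texture
coordinates come from projecting each vertex into the color sensor (offset
~25 mm laterally). A triangle whose uv-space signed area is non-negative
has flipped between the two sensors' viewpoints — it bridges an occlusion
and is removed. Degenerate texture footprints (uv area < 0.25 px²,
shortest uv edge < 0.5 px, beyond the texture's top/bottom) are removed,
then skinny triangles: smallest angle below 13° *and* both long edges
exceeding the mean + 4 sd of the edge lengths of triangles within
`max(0.9·|e_b|, |e_a|)` of the tip vertex or the short-edge midpoint.
Removal cascades to adjacent skinny triangles over the long edges; when a
triangle has two sub-13° angles and only the longest edge is an outlier,
just the neighbour sharing that edge is removed. Duplicate vertices
(exact coordinate equality — depth quantization makes near-duplicates
legitimate), unreferenced vertices, and connected patches below 100
triangles are cleaned up last.

The canonical patient frame permutes camera axes (+z toward the head, +x
patient right→left) and places the origin on the camera's central viewing
axis at the depth of the shoulder medians: the mean of the median depths
of the outer two of five lateral subgroups within the top third of the
torso. A surface whose longest extent is already along z is assumed
canonical and only re-centered, which makes the operation idempotent.

## Registration

Pairs of consecutive views are aligned by symmetric point-to-plane ICP.
Surfaces are voxel-downsampled at 6 mm — each cell contributes the
*centroid* of its vertices, which suppresses the raw depth noise by the
cell occupancy — and normals are re-estimated at that scale by local PCA
(10 neighbours), sign-aligned with the mesh normals. Single-vertex normals
of a noisy fine mesh are too unstable for point-to-plane residuals.

Initialization estimates the relative z-rotation from the two views'
shoulder medians, then shifts the source so the centers of mass inside the
overlapping bounding box align. The correspondence schedule starts at
`l_c = l̄ + 2σ_l` over normal-compatible (within 30°; a 0.98-dot variant
is selectable) forward/backward nearest neighbours, with `σ_l0` their
spread and `l_min` the mean nearest-neighbour spacing floor (1 mm).

Each outer run performs a forward ICP (cap 50 iterations, stopping when
the plane-residual rmse changes by less than `1e-6` relative or `1e-4` mm
absolute) and a reverse ICP initialized at the forward inverse. The
candidate with lower error *and* tighter updated correspondence distance
is accepted per the symmetric criterion; when the two directions split the
criteria (one wins on error, the other on distance), the lower-error
candidate is accepted provided it still improves both quantities over the
current state — without this tie-break the iteration can stall after a
single round. On failure, one final run at `l_c = l_min` is attempted if
the last accepted tightening exceeded `σ_l0`. Inside the loop,
correspondences onto boundary points of the target (8th neighbour beyond
2.2 voxel pitches) are excluded and the worst 10% of plane residuals are
trimmed — standard partial-overlap safeguards. Global poses are the
cumulative products of the pairwise transforms, with the first view as
reference (an optional flag initializes it from the frontal plane).

## Markers, model fit, grid, labels

Classification uses rotated ellipses in (r, g) chromaticity with σ²
denominators (consistent with the gray-pixel test); red wins ties. Pixels
lift to 3D through the barycentric coordinates of the uv triangle that
contains them; pixels outside every triangle are dropped. Red points
survive only with a blue neighbour within the clip-head radius (7 mm =
disk 5 mm + ring 2 mm; the physical clip dimensions are configuration,
chosen at plausible clip scale), blue only with a red neighbour within the
ring width.

Clustering is HDBSCAN — implemented in the package (mutual-reachability
minimum spanning tree in C++, condensed tree and excess-of-mass selection
in R, validated against an independent reference implementation on planted
mixtures) — with minimum cluster size `max(n_red/(4·N_clip), 20)`, minimum
samples 20, and a split-stopping distance equal to the clip-head radius,
so one marker is never split while adjacent markers (≥ 2 cm apart in any
sane layout) still separate.

The marker model is fitted per cluster after projecting the points onto
the plane of the dominant normal (singular directions within three decades
of the leading one are kept; the unit mean of the truncated reconstruction
is the normal; a near-zero mean flags an ambiguous, e.g. opposing, bundle).
The objective penalizes blue points by `(ρ − ρ_disc)²`, red points only
*outside* the disk by the same measure, plus the squared out-of-plane
offset of the center; L-BFGS-B starts at the centroid with bounds of twice
the clip diameter. A half-occluded ring biases the center toward the
present arc by roughly the ring's radial offset times 2/π (~1 mm at this
geometry); complete rings are unbiased. Clusters with unbalanced red/blue
counts (ratio outside 1/3–3) are split candidates and merge when at least
10 points of each have their nearest out-of-cluster neighbour in the
other; the model is then fitted to the larger piece only.

Ball pivoting over the fitted centers uses radii `x̄/2` and `x̄` from the
mean 9-nearest-neighbour spacing. Centers whose spacing statistic exceeds
`x̄ + 2σ` are excluded from that statistic but not deleted — single
electrodes always violate it and must survive to be labeled. Triangles are
accepted by the empty-ball criterion (enumeration over triples is exact at
these sizes). Near-duplicate centers (closer than 2/3 of the clip-head
radius) collapse onto the larger connected group, iteratively. The two
largest connected meshes are the electrode patches; the patch with the
smaller mean y (anterior) is frontal. Rows are split at z-gaps larger than
half the dominant vertical pitch (10 mm floor); frontal channels run
bottom-right to top-left, dorsal channels continue top-right to bottom-left
(right/left in patient coordinates). Singles classify as the Einthoven
electrodes (right/left shoulder, left hip) and the two right-side
auxiliaries using directions relative to the electrode centroid and the
frontal patch — this stays correct under the residual yaw that the
frontal-plane realignment can leave on partial angular coverage (the
shoulder-median method has a coverage-asymmetry bias of up to ~25° when a
quadrant of the torso is unscanned; all later steps are built to tolerate
it, and the final evaluation aligns rigidly to the reference frame anyway).

## Calibration

The red/blue ellipses come from a 256×256 heat map over (r, g) of
manually masked clip pixels (properly exposed only), median-filtered 7×7.
Peaks are 4-connected regions of at least 5 bins above the mean + 1.9 sd
of the nonzero bins ("nonzero" is the reading adopted for the norm in the
threshold rule). A full-covariance Gaussian mixture with one component per
peak — a small weighted EM on the binned counts, initialized at the peak
centroids; packaged mixture fitters do not handle count-weighted bins —
yields the components. The one with the largest mean r is red; the one
maximizing `1 − r − g` is blue; others (specular highlights, raw-conversion
artefacts) are discarded. Ellipse spreads are the square roots of the
covariance eigenvalues (the eigenvalues are variances, the ellipse axes
standard deviations) and the rotation comes from the leading eigenvector,
kept in (−90°, 90°]. Components that straddle the chromaticity simplex
boundary are recovered as the moments of the truncated cloud — the fit
cannot know about mass outside the physical domain.

## The synthetic scenes

The generator renders what the validation needs and no more:

* **Geometry.** An elliptic cylinder (rx = 160, ry = 105, height 500 mm)
  with two ingredients that make it body-like where the pipeline needs it:
  low-amplitude relief harmonics (wavelengths ≈ 110/70/45 mm, ~5 mm peak,
  conservative against real muscle/rib relief) that lock ICP along the
  axis and azimuth, and an ellipsoidal shoulder dome above 72% height that
  gives the shoulder-median logic a real feature. No arms, neck, head,
  breathing or cloth.
* **Electrodes.** 67 by default: frontal 8×4 and dorsal 6×5 patches at
  32 mm spacing, three Einthoven singles and two right-side auxiliaries
  (the five singles are placed ≥ ~100 mm from the patches so ball
  pivoting cannot bridge them; the smaller 32- and 8-electrode layouts
  drop the singles). Markers are painted as red disk (5 mm) plus blue
  ring (2 mm) around the exact surface points.
* **Acquisition.** Analytic ray casting (quadratic base intersection plus
  Newton refinement onto the modulated surface) from a 320×426 portrait
  pinhole pair with a 25 mm color baseline at ~550 mm range — a
  scaled-down stand-in for a short-range depth/color module, sized so the
  default validation runs in minutes on one CPU. A gray wall behind the
  torso supplies the gray pixels white balancing needs; its chromaticity
  jitters along the red–blue axis (illuminant-like variation) with the
  green coordinate fixed, and intensities span most of the exposure band.
  Per-view illuminant casts go through the same gain model the
  white-balance stage assumes, with the recorded setting clamped to the
  sensor range (emulating the online controller); depth gets Gaussian
  noise (default σ = 1 mm), millimetre quantization, and an invalid band
  at large discontinuities.

Because the casts follow the assumed gain model exactly and the gray wall
is statistically neutral, the white-balance loop converges to machine-level
gamut errors here; real sensors add spectral effects the model cannot
cancel. Likewise the ~0.5–1 mm end-to-end positional errors on clean
synthetic scenes show the pipeline's internal consistency, not clinical
accuracy — posture change, skin deformation, specularities and marker
occlusion by cables dominate on real patients.

## Problem sizes and determinism

The shipped validation uses 14 views at 320×426 (≈ 55k vertices per view
after masking), registration clouds of ≈ 6k points, and ≈ 20k marker
points; this keeps the complete suite in the minutes range on a single
CPU. All stochastic steps are seeded; the generator's default seed is
1234 and each test fixes its own seed. The mixture EM and all geometry are
deterministic given the data.

## Known limitations

* The offline color correction refines a tracked white balance; it cannot
  recover an arbitrary untracked cast (no gray pixels survive selection).
* The frontal-plane realignment inherits the coverage bias discussed
  above; labeling is robust to it, but the reported map's frame can be
  yawed relative to the anatomical frontal plane by tens of degrees when
  coverage is very asymmetric.
* Labeling assumes the layout family it was built for (two rectangular
  patches plus up to five singles); other montages need their own scan
  order.
* Ball pivoting by triple enumeration is exact but cubic in the number of
  electrodes — fine for hundreds, not for thousands.
* The synthetic torso has no arms; the Einthoven "shoulder" singles sit on
  the front of the shoulder dome instead.
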