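# electrodecam

Localization of body-surface ECG electrodes from the recordings of a 3D
depth-sensing (depth + RGB) camera — fully offline, without the camera
hardware.

Electrophysiological models of the heart (noninvasive imaging of cardiac
electrophysiology, body-surface potential mapping) need the 3D positions of
tens to hundreds of ECG electrodes on the torso to a few millimetres. CT and
MRI localization is accurate but costly or dose-limited; magnetic digitizers
need ~15 min of careful pointing per patient. A handheld depth-sensing
camera can instead record 12–15 overlapping views of the torso in a couple
of minutes, and the electrode positions can be recovered from the recordings
alone. This package implements that full recovery pipeline for electrode
clips carrying a circular fiducial: a red disk (the epoxy clip head) inside
a blue ring (the painted rim).

## What the pipeline computes

Given per-view pairs of a 16-bit depth image `D16` (mm, 0 = undefined) and a
gamma-compressed RGB image with the color-temperature setting `K_W` each was
recorded at:

1. **Color normalization.** Channels are linearized through the sRGB curve
   and split into chromaticity `(r, g, b) = (R, G, B)/I` and intensity
   `I = R + G + B`. Gray pixels are those inside two ellipses around the
   neutral 5500 K gamut point `(r̄, ḡ, b̄) = (0.363, 0.338, 0.299)` and
   inside the linearized exposure band `(0.00155·I_max, 0.955·I_max)`. The
   sensor's gains follow `Γ_R = Γ_K`, `Γ_B = 1/Γ_K` with
   `Γ_K = sqrt(2 (K_W − K_min)/(K_max − K_min))`; the gain scaler that
   moves the mean gray chromaticity onto the neutral point is
   `γ = sqrt( (r̄ · b̄_W) / (r̄_W · b̄) )`. Offline, a virtual camera with
   an extended range (2000–9000 K) re-runs this white-balancing loop on
   each stored texture until the numeric stopping test
   `(E > 1.758e-8) ∧ (E − E* > 1e-15)` fails, which also corrects shaded
   scenes beyond the physical sensor range.
2. **Exposure scoring.** The skewness of the gray-value histogram of the
   patient-masked pixels, computed by left bisection over precomputed
   linearized bin boundaries, drives the exposure controller
   `τ*_{n+1} = τ*_n − S(V)·τ_Δ·N_τ·Γ_ex` (and scores frames offline).
3. **Depth segmentation.** Gradient-weighted table-driven smoothing, an
   octagonal Laplacian zero-crossing detector with Canny-style primary
   (1.2 cm) and minor (0.35 cm) limits, 4-connected component selection in
   the central image segment with flood-fill extension, and a per-row
   depth band `D_close < D_i < D_far` built from row minima/maxima.
4. **Meshing.** Pinhole backprojection onto a pre-triangulated grid;
   triangles whose winding flips between the depth geometry and the color
   sensor's uv projection are occluded and removed, along with degenerate
   (uv area < 0.25 px², shortest uv edge < 0.5 px) and skinny triangles
   (smallest angle < 13° with outlier edge lengths against their local
   neighbourhood); the surface is then placed in the canonical patient
   frame (+z head, +x right→left, origin on the camera axis at the
   shoulder-median depth).
5. **Registration.** Pairwise *symmetric* point-to-plane ICP: forward and
   reverse runs, the candidate with lower error *and* tighter
   correspondence distance `l_c,+1 = l̄ + 2σ_l` is accepted until the
   schedule bottoms out near 1 mm. Initialization uses the relative
   shoulder-median rotation `Δφ` and bounding-box-overlap centroids.
   Global view poses are chained cumulatively.
6. **Marker extraction.** Red/blue pixels are classified with calibrated
   rotated ellipses in (r, g) chromaticity, lifted to 3D through
   barycentric coordinates of their uv triangle, filtered by
   opposite-color proximity, and clustered per electrode with HDBSCAN
   (minimum cluster size `max(n_red/(4·N_clip), 20)`, split-stopping
   distance = clip-head radius).
7. **Model fit and labeling.** Each cluster is projected onto the plane of
   its dominant normal (rank-truncated SVD of the normal bundle) and the
   disk/ring model is fitted by L-BFGS-B; split markers merge through
   mutual-nearest-neighbour pieces; ball pivoting over the fitted centers
   (radii `x̄/2` and `x̄` from the mean 9-NN spacing) separates the
   frontal and dorsal patches from the single electrodes; channels are
   numbered bottom-right→top-left on the chest, continuing top-right→
   bottom-left on the back, and the singles are classified as the
   Einthoven and right-side auxiliary electrodes.
8. **Calibration.** The marker-color ellipses themselves come from a
   median-filtered 256×256 chromaticity heat map of masked clip pixels:
   peaks above `n̄_H + 1.9 σ(n_H)` seed a Gaussian mixture whose red/blue
   component covariances give the ellipse spreads and rotations.

A synthetic-scene module renders ground-truth torso scenes (elliptic
cylinder with body-scale relief and a shoulder dome, 67 electrodes in the
frontal 8×4 / dorsal 6×5 / 5-singles layout, per-view illuminant casts
through the same gain model, depth noise and quantization) so that every
stage and the end-to-end pipeline are testable without hardware.

## Worked example

Render a 14-view scene of a 67-electrode torso with per-view color casts
and 1 mm depth noise, then run the whole pipeline against the known ground
truth:

```r
library(electrodecam)

model <- make_torso()                       # 67 electrodes, known positions
cam   <- default_camera()                   # 320 x 426 portrait pinhole pair
poses <- default_poses(model, n_views = 14) # 270 degrees around the torso
set.seed(99)
views <- render_views(model, poses, cam,
                      k_true = runif(14, 3500, 8000),  # illuminants per view
                      depth_sigma = 1, seed = 42)

res <- run_pipeline(views, cam, truth = ground_truth(model), n_el = 67)
res$evaluation$mean_error
#> [1] 0.6224503
res$evaluation$sd_error
#> [1] 0.2754417
sum(res$evaluation$per_electrode$label_correct)
#> [1] 67
res$map
#> Electrode map: 67 electrodes (32 frontal, 30 dorsal, 5 single)
```

All 67 electrodes are detected and correctly labeled; after rigid
alignment to the ground truth the mean positional error is 0.62 mm ±
0.28 mm (the synthetic scenes are cleaner than clinical recordings, whose
reference error scale is about 2 mm). `res$registration` holds the
per-pair alignment report (runs, initial/final correspondence distance,
rmse in mm), `res$exposure` the per-view exposure scores, and
`autoplot(res$map)` draws the labeled front/back electrode layout.

A thin command-line driver for the same steps ships in
`inst/cli/electrodecam.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/electrodecam.R", package="electrodecam"))')" \
    simulate /tmp/scene --views 14 --seed 7
Rscript .../electrodecam.R run /tmp/scene /tmp/out
```

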