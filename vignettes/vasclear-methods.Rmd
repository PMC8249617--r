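---
title: "Methods: vascular tracing and tracer extravasation quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vascular tracing and tracer extravasation quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model of the data

`vasclear` quantifies fluorescence microscopy of brain-tumor vasculature in
two regimes:

* **3D volumes of optically cleared tissue** (light-sheet / confocal
  Z-stacks), with a vessel-wall label (lectin) in one channel and an
  intravascular tracer (dextran or albumin) in another. Anisotropic voxels
  are the norm; the reference calibration is 0.69 × 0.69 × 3 µm (x, y, z).
* **2D slide scans of sections** after transcardial perfusion, where each
  vessel segment is classified by how completely it was flushed:
  non-perfused (tracer only), underperfused (both labels, dimmer tracer),
  perfused (wall label only), on top of background.

All image-space filter sizes below are quoted in *pixels* of the
uncalibrated image, as is conventional for these workflows; all outputs are
in physical units (µm, µm², µm³; branch density per mm³). The package
assumes the 8-bit intensity convention: every threshold is on the 0–255
scale, and masks are scaled to {0, 255} before Gaussian re-thresholding so
those thresholds are meaningful.

# Pixel classification

Commercial trainable segmentation (pretrained-CNN features feeding a random
forest) is replaced by the same architecture with reproducible parts: a
**fixed multiscale filter bank** — per scale *s*: Gaussian, gradient
magnitude, Laplacian, two Hessian eigenvalues, two structure-tensor
eigenvalues, optionally a difference-of-Gaussians — feeding a **bagged CART
forest** (default 100 trees, unlimited depth, `mtry = sqrt(p)`,
out-of-bag accuracy reported). Only the forest is trained; the features are
fixed and documented. Training pixels are taken from sparse scribble masks
in canonical scan order, which makes the fit invariant to how the caller
assembled the annotations. 3D stacks are classified slice-wise with 2D
features, matching how such stacks are annotated in practice; multi-channel
images contribute one filter bank per channel.

Structured postprocessing (conditional random fields) is out of scope; an
optional Gaussian smoothing of the probability stack before the argmax is
provided as a lightweight stand-in and is **off by default**.

The forest is implemented in compiled code inside the package because the
target environment provides no random-forest package; it is deterministic
given its seed.

# Extravasation spots (3D)

The pipeline follows the published five stages:

1. *Preprocessing*: optional Richardson–Lucy deconvolution with a
   parametric anisotropic Gaussian PSF (a stand-in for blind
   deconvolution), then a 2D Gaussian blur, σ = 1.3 px.
2. *Segmentation*: trained classifier (or a plain intensity threshold for
   phantom work).
3. *Postprocessing*: four consecutive per-slice 3 × 3 dilations, mask
   scaled to {0, 255}, 3D Gaussian with σ = 3 px in x, y and z, threshold
   50–255.
4. *Spot recognition*: 26-connected 3D components, each measured in
   physical units (volume, exposed-face surface area, unweighted centroid,
   bounding box, mean source intensity).
5. *Filtering*: spots **strictly smaller** than 10,000 µm³ are excluded (a
   spot exactly at the bound is kept). This rejects the axially elongated
   bright artifacts caused by out-of-focus light along the PSF z-axis,
   which rarely exceed that volume.

A geometric note that matters for interpretation: the
dilate–blur–threshold stage adds a predictable margin of roughly
`n_dil · px + Φ⁻¹(1 − 50/255) · σ · px` per axis (about +4.5 µm in-plane
and +7.7 µm axially at the reference calibration). For *fragmented*
segmentations — the stage's purpose is to glue fragments — this
approximately restores the true spot envelope; for an already-solid input
object it strictly inflates it (≈2× in volume for a 20 µm sphere). The
tests therefore validate the stage against the analytic margin envelope,
not against the fiction that a solid sphere passes through unchanged.
Because the margins are in pixels, measured artifact volumes stay below the
10,000 µm³ bound only at calibrations near the reference voxel size; the
phantom world uses exactly that calibration.

The albumin mode is simpler: threshold the tracer channel (60–255),
subtract the postprocessed vessel mask, and report the extravascular volume.

# Vasculature (3D)

Postprocessing of the segmented vessel mask: scale to {0, 255}, 3D Gaussian
σ = 0.9 px, threshold (170–255 for tumor data, 105–255 for normal brain),
**lumen filling**, then a 3D median filter (radius 3 px tumor, 1 px normal
brain).

*Lumen filling*: large vessels are segmented as hollow tubes because the
label binds the wall. For each slicing orientation (XY, YZ, XZ, in order)
and each slice, 4-connected background components that do not touch the
slice border and whose physical area lies within an adjustable range are
set to foreground; the sweep is repeated twice. The area range guards
against filling the space *between* small vessels; the default range is
[4 in-plane pixel areas, π·(50 µm)²] — the upper bound admits lumens of
vessels up to ~100 µm diameter, which covers the large vessels this step
exists for. A lumen that is open (C-shaped) in one orientation is caught by
an orientation in which its contour closes. A brute-force border-flood
oracle with identical semantics ships in the package and the two are held
to exact agreement on randomized volumes.

*Tracing*: the mask is resampled to an isotropic lattice (linear
interpolation to the smallest spacing, re-binarized at 0.5) because
homotopic thinning on anisotropic lattices distorts centerlines. The
skeleton is obtained by distance-ordered homotopic thinning: voxels are
visited in increasing Euclidean-distance-transform order and deleted when
they are simple points for (26, 6) connectivity and not curve endpoints.
Skeleton voxels become a spatial graph (junction = degree ≥ 3, endpoint =
degree 1; adjacent junction voxels are clustered into one node). Per-point
radius is the distance-map value at the skeleton point; segment length is
polyline arc length; tortuosity — which the source workflow never defines —
is arc length divided by endpoint chord length. Terminal twigs shorter than
10 µm are pruned first, degree-2 chains are then merged, and any remaining
segment below the bound is excluded, so every retained segment is ≥ 10 µm.

*Diameter correction*: thinning-based tracing systematically underestimates
small-vessel diameters. The correction factor
`CF(MD) = (Y0 − Plateau)·exp(−K·MD) + Plateau`, with the published
calibration Y0 = 3.7, Plateau = 1.3, K = 0.5861 µm⁻¹, multiplies the
initially measured diameter MD. We correct per segment, with MD the segment
mean diameter (the per-point alternative is not what the calibration was
fitted on). `fit_diameter_correction()` refits the model from (MD,
reference diameter) pairs by multi-start nonlinear least squares; noiseless
self-consistency is recovered to 1e-6. With 5 % multiplicative noise at
n = 100 the single-draw spread of Y0 and K is itself of order 5–10 %
(few calibration vessels are thin enough to constrain Y0), so recovery is
assessed as a median over a fixed-seed Monte-Carlo.

*Summaries*: vascular volume fraction (mask volume / tissue volume), mean
segment diameter/length/tortuosity, junction count and density per mm³
(the alternative "branch segments" count is not reported), and a
volume-fraction histogram over diameter bins in which per-segment cylinder
volumes are rescaled to sum exactly to the total volume fraction.

# Perfusion degree (2D)

Per section: class areas within an optional ROI as pixel counts × pixel
area; percentages over the three vascular classes only. Tumor-level
summaries weight each section by its total *vascular* area — the published
description ties the weight to the area underlying the per-section
percentages; equal weighting is available as an alternative. The weighted
average provably equals quantification of the pooled mosaic when pixel
areas agree, and the tests assert exactly that. An arcsine square-root
transform is provided for downstream regression; the regression itself is
deliberately out of scope. Mean tracer intensity per class supports the
non-perfused vs underperfused contrast.

Tissue shrinkage: `CF = med(OCS) − med(CPS)` from per-sample volume-change
percentages (optically cleared vs conventionally prepared samples;
defaults emulate the reported ~−71 % and ~−12 %); volumes measured in
cleared samples are rescaled by `(100 + med(CPS))/(100 + med(OCS))` to
sectioned-sample equivalents. The direction of the correction is a package
decision — the source states the correction but not its direction — chosen
so that spot densities from cleared material are comparable to sectioned
material.

# The phantom world

Every stage is tested against a seeded generator with exact ground truth;
no imaging data ships with the package.

* **Vessel phantoms**: tubes along momentum-smoothed random walks
  (two 3-point smoothing passes bound the curvature, keeping per-segment
  tortuosity analytic and modest), rendered in physical space and sampled
  at the requested anisotropic spacing. Tubes with radius > 8 µm are
  wall-only (3 µm wall) — the hollow-tube appearance of large vessels;
  smaller tubes are solid. Intensities are 8-bit, with depth attenuation
  `exp(−a·z)` (a = 0.001/µm), optional Poisson shot noise and additive
  Gaussian read noise (sd 8). Default lattice: 40 × 320 × 320 voxels at
  3 × 0.69 × 0.69 µm — the reference calibration, deliberately, because
  the pipelines' pixel-unit filter sizes only carry their intended physical
  meaning there.
* **Spot phantoms**: ellipsoidal blobs (semi-axes r·U(0.9, 1.1), r in
  17–21 µm) placed within two radii of a vessel centerline, with analytic
  volumes recorded; separate bright z-spindles (extent 30 µm, true volume
  400–1500 µm³) seeded on vessel voxels emulate PSF artifacts. Spots are
  distinct leakage events, so placement enforces a 30 µm separation margin
  — wider than the postprocessing margin — preventing artificial merging.
  If space runs out, fewer spots are placed and the count is reported.
* **Perfusion slides**: 2D strokes greedily assigned to the class whose
  pixel share is furthest below target, so realized class fractions land
  within a few percent of the requested proportions; class-specific
  channel intensities encode the labeling logic (underperfused dextran
  drawn dimmer than non-perfused).

What a green phantom test does *not* establish: realism of tumor histology,
scattering or optics (the attenuation and spindle models are stand-ins),
stitching artifacts, or 60-GB-scale out-of-core behavior. The phantoms
exercise geometry, calibration, and the stated filtering semantics.

# Numerical choices

* Coordinates: 0-based voxel indices; physical position = index × spacing
  (voxel-corner origin). One convention everywhere prevents half-voxel
  drift between modules.
* Gaussian filters: separable, kernel radius 4σ, reflective boundaries
  (this is what keeps Richardson–Lucy flux-conserving to < 1 %).
* Median filter: spherical neighborhood, in-bounds part at borders.
* Distance transform: exact squared-distance lower-envelope method with
  per-axis spacing weights.
* Thresholds are inclusive ranges `[lo, hi]` on 0–255.
* Size-filter boundary: keep iff volume ≥ bound ("smaller than" excludes).
* 3D component connectivity defaults to 26 (most permissive, matching the
  glue-fragments intent); hole filling uses 4-connectivity in-plane, the
  complementary convention.
* Ties in the forest argmax resolve to the lowest class index; forests are
  seeded and independent of R's global RNG. Generators seed locally and
  restore the caller's RNG state.
* TIFF I/O: the package carries a minimal baseline-TIFF codec
  (uncompressed grayscale 8/16-bit, resolution tags + ImageJ-style
  description for spacing) because the target environment provides no TIFF
  package; RGB, palette, compressed and tiled files are rejected
  explicitly. Rational resolution tags quantize spacing at ~1e-7 relative
  error.

# Known limitations

* The skeleton is a curve skeleton; sheet-like segmentation errors are
  summarized as thick segments rather than surfaces.
* Diameter correction assumes the published calibration transfers; refit
  with `fit_diameter_correction()` on your own paired measurements when it
  does not.
* Slice-wise 2D features ignore axial context; 3D features are a possible
  extension, not implemented.
* The CLI loads whole stacks in memory; very large volumes should be
  cropped upstream.
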