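---
title: "Optic nerve segmentation and morphometry: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optic nerve segmentation and morphometry: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

On high-resolution 3D T2-weighted MRI the optic nerve (ON) appears as a
thin dark tube running from the bright eye globe to the optic chiasm,
surrounded by a bright sheath of cerebrospinal fluid (CSF) of variable
thickness. Because the nerve bends toward the chiasm, its apparent size in
the fixed coronal plane overestimates its true cross-section by roughly
1/cos θ, where θ is the local angle between nerve and the coronal normal.
`onquant` therefore (a) segments the nerve *without* its CSF sheath with a
3D U-Net and (b) measures diameter and cross-sectional area perpendicular
to an extracted centerline, every 0.1 mm along the nerve.

All grids are axis-aligned RAS (x right, y anterior, z superior); the
coronal plane has unit normal v_cor = (0, 1, 0). `read_nifti()` /
`write_nifti()` implement single-file NIfTI-1 with an sform affine — no R
NIfTI package is required.

# The synthetic world

No public data exist for this anatomy at this resolution, so every stage is
validated on phantoms (`phantom_spec()`): a natural cubic spline through
ordered control points (chord-length parameterization, arc-length resampled
at ≤ 0.05 mm), swept with a piecewise-linear radius profile r(s) and CSF
shell thickness t(s), composited as background / globe / CSF / nerve
intensity levels, multiplied by a low-order polynomial bias field and
corrupted by seeded Gaussian noise. Masks are analytic (voxel center within
r(s) of the curve, flat-capped at both ends) and never noised; the truth
object stores the centerline, r(s), and a(s) = πr(s)² exactly.

Default intensity levels (background 50, nerve 100, CSF 300, globe 280,
noise σ 10) reproduce the qualitative T2 contrast: CSF ≫ nerve > background.
Radius (1.1–2 mm) and sheath (0.3–0.8 mm, thinning posteriorly) follow the
pediatric anatomy the pipeline targets; radius and thickness knots are
placed at *relative* arc length (0–1) so seeded cohorts with varying curve
lengths share one profile language. Two phantom families are used: a 64³
voxel (19.2 mm) single-nerve VOI for network training, and an ~37 mm
globe-to-chiasm nerve for geometry recovery, matching the anatomical length.
What the generator does **not** emulate: partial-volume fraction maps, MR
physics (no Rician noise, no susceptibility), pathology, motion. A green
test therefore establishes geometric and statistical correctness of the
machinery, not clinical performance.

# Preprocessing

* **Eye detection** — gradient-direction spherical Hough voting: voxels
  with gradient magnitude above a data-derived threshold vote along their
  gradient direction at radii 9–14 mm (a documented guess for pediatric
  eyes; exposed as `radius_range`) into a 2 mm accumulator, Gaussian
  smoothed (1.5 mm); the two strongest peaks at ≥ 20 mm separation are
  refined by intensity-weighted centroids. Fewer than two candidates above
  30% of the top score → "eyes not found".
* **Rotation rule** — the angle between the inter-centroid vector and the
  lateral axis, measured in the axial plane, is corrected only when > 5°
  ("realignment … if the angle was greater than five degrees"); rotation and
  resampling to 0.3 mm isotropic are one composed transform (linear for
  intensities, nearest-neighbour for masks) so no intermediate interpolation
  occurs. Axial in-plane rotation is an interpretation: the rule is defined
  by the two eye centroids, which only constrain the axial plane.
* **VOI** — 144×240×112 voxels per eye (≈ 43×72×34 mm at 0.3 mm): ~50 mm
  posterior / 20 mm anterior of the mid-centroid point, ~17 mm
  superior/inferior, ~45 mm lateral on the chosen side. Out-of-volume crops
  pad with the 1st-percentile intensity (phantoms can be small; clinical
  head scans never pad) and warn.
* **Bias hook** — full N4 is out of scope; `flatten_bias()` divides by a
  unit-mean exp-polynomial (order ≤ 2) fitted to the log-intensities of
  background-like voxels (2nd–95th percentile band, outlier-trimmed refit).
  An external N4 can simply replace the input volume.

# Segmentation network

Standard 3D U-Net: per level two 3×3×3 convolutions each followed by batch
normalization and ReLU; 2×2×2 stride-2 max-pooling down, 2×2×2 stride-2
upconvolution + skip concatenation up; final 1×1×1 convolution + sigmoid.
Full-size config: depth 5, features 32→512, input 144×240×112. Training
recipe: Adam, lr 1e-3, batch size 1, soft Dice loss (ε = 1 in numerator and
denominator — standard stabilization for empty masks), up to 150 epochs,
early stop after 40 epochs without validation improvement, best-validation
checkpointing. Augmentation: isotropic content scaling 0.8–1.2 (p = .5,
linear/nearest, recropped to shape), left-right flip (p = .5),
multiplicative intensity scaling 0.5–1.5 (p = .3; the range brackets 1, so
a gain factor), additive Gaussian noise σ = 0.1 (p = .3), Gaussian blur
σ = 0.2–1.2 voxels (p = .3).

Implementation notes (no deep-learning library exists in the target
environment; layers and backprop are hand-built in RcppArmadillo, float32,
convolutions as 27 shifted GEMMs):

* With batch size 1, "batch" normalization statistics are the per-channel
  spatial moments of the sample, used identically at training and inference
  — deterministic prediction, no running averages.
* The output bias is initialized to −4: the tube is ~1% of the voxels and a
  neutral sigmoid start stalls the Dice loss for many epochs.
* The CPU-tested path is depth 3, base 8 features, 64³ input ("toy"); the
  depth-5/base-32 configuration is constructed and shape-checked but not
  trained in tests (GPU-scale). Depth 3 is a deliberate toy choice: the
  acceptance budget is 15 CPU-minutes and the phantom task saturates well
  below depth 5.
* Per-subject (not per-eye) validation splits are recommended when both
  eyes of a subject are used; the trainer takes explicit sample lists.

Postprocessing keeps the largest 26-connected component (removing stray
distant misclassifications); equal-size ties keep the component whose seed
voxel comes first in column-major raster order — deterministic.

# Evaluation metrics

DSC, precision and recall are voxel-count ratios. The tolerance DSC counts
a disagreeing voxel as agreeing when it lies within one voxel of the other
mask's surface (it joins both the intersection and the union — this keeps
the score ≤ 1, reduces to plain DSC at tolerance 0, and scores a one-voxel
shift as 1). HD95 and ASD operate on *surface voxels* (mask voxels with a
face-adjacent background neighbour; the grid border counts as background),
center-to-center distances in mm, directed 95th percentiles by linear
interpolation (type-7). Both-empty DSC is defined as 1, one-empty as 0.
ICC(A,1) is the McGraw–Wong two-way mixed-effects absolute-agreement
single-rater coefficient, computed from the explicit ANOVA decomposition.
All of these are checked against exhaustive brute-force oracles in the test
suite.

# Centerline and cross-sectional profile

* **Surface** — marching tetrahedra (Kuhn 6-tet split, face-consistent,
  watertight even at grid borders) at the 0.5 level of the binary mask
  convolved with a σ = 0.75-voxel Gaussian. The presmoothing is *vertex
  placement*, not mesh smoothing: binary-lattice isosurfaces overestimate
  area by up to ~8% orientation-dependently, while the Gaussian's
  curvature-driven shrink at these radii is ≈ σ²/2r ≲ 1%. Optional Taubin
  λ|μ smoothing is off by default — surface-model smoothing is the
  documented mechanism behind systematic size underestimation in
  Slicer-style pipelines, and the tests assert its shrinking effect.
* **Endpoints** — geodesic farthest-point pair by double Dijkstra sweep,
  each end re-centered as the centroid of its end region (within 1 mm of
  the maximal geodesic distance), which moves it from the cap rim onto the
  axis. This is a stand-in for the automatic endpoint heuristic of
  vascular-modeling toolkits, whose algorithm is not published; manual
  endpoints override it.
* **Centerline** — Dijkstra shortest path on the 26-connected interior
  graph under node cost 1/(ε + d²) with d the distance-to-boundary in
  voxels and ε = 0.1 voxel: the quadratic exponent pushes the path onto the
  distance-field ridge, approximating the Voronoi/maximal-inscribed-sphere
  centerline. The raw voxel path is resampled, re-centered on the in-plane
  distance ridge (interior samples only — near a flat cap the medial
  surface bends into a disc and re-centering there would drag the endpoint),
  Gaussian-smoothed along arc length (σ 0.6 mm), extended along the end
  tangents to the mask boundary, and resampled at exactly 0.1 mm. The
  inscribed radius is measured against the surface mesh (sub-voxel) when
  available, else the voxel distance field.
* **Profile** — at each sample the plane through the point with the tangent
  as normal cuts the mesh; triangle-plane segments are chained through
  shared mesh edges into closed polygons (coplanar vertices are ε-perturbed
  by 1e-9 mm for determinism); the polygon containing the point is used,
  else the nearest-centroid polygon with a `"nearest"` flag. d_CE =
  2√(a/π) holds to machine precision by construction; d_MIS = 2·inscribed
  radius. Samples within two (median) radii of either end are flagged
  `"cap"` — plane sections near tube caps are unreliable and real
  measurements start at the most anterior CSF, never at the cap. More than
  10% invalid interior samples is an error, not a silent drop.

Measured accuracy on phantoms (see tests): cylinder d_CE within ~1.5%,
arc length within ~1%, orientation invariance within 0.5%; elliptical
sections separate d_CE (2√2 mm) from d_MIS (≈ minor axis, ± one voxel).

# Comparison module

* **Coronal ablation** — a_cor is the in-plane 8-connected component area
  of the mask in the coronal slice through each centerline point; a_corr =
  a_cor·(c_i·v_cor) and θ = arccos(c_i·v_cor) exactly as the correction
  formula prescribes; samples with θ ≥ 85° (centerline nearly parallel to
  the coronal plane) are flagged and excluded from averages, as are cap
  samples. The relative error of the coronal equivalent diameter,
  √(a_cor/a_cs) − 1, behaves as 1/√cos θ − 1.
* **Offset alignment** — manual references live at the most anterior CSF
  and +3/+5 mm; the model origin differs, so the offset in [0, 1] mm
  minimizing the MAE over the three points is searched on the profile grid
  (0.1 mm — the search step is not stated in the original protocol; the
  profile step is the natural choice). Ties take the smaller offset.
* **Agreement** — MAE, ICC(A,1), Bland–Altman mean difference ± 1.96 SD.
* **Intensity baseline** — the "fit the coronal intensity profile" family
  of methods is represented by a radial forward model: dark disc (radius
  r_on) + bright annulus (to r_csf) + background, convolved with an
  isotropic Gaussian, least-squares fitted (Nelder–Mead, multi-start over
  r_on scales {0.8, 1, 1.25}, simplex restarts until stable, soft box
  penalty keeping levels in the data range). The published description
  names both a Gaussian-mixture and a difference-of-Gaussians fit without
  equations; this forward model is an interpretation, not a faithful port —
  what is reproduced faithfully is the *failure mode*: a quality flag is
  raised when the fitted annulus is not distinctly brighter than the disc
  (absent CSF) or angularly inhomogeneous across quadrants (asymmetric
  CSF), the regimes where intensity-only methods break on high-resolution
  data.

# Numerical choices and degenerate inputs

* Soft-Dice ε = 1; BN ε = 1e-5; marching-tetrahedra interpolation clamps t
  to [1e-6, 1 − 1e-6] (no degenerate triangles); plane-section coplanarity
  ε = 1e-9 mm; offset and tolerance comparisons carry a 1e-9 guard against
  float ties.
* Empty masks: DSC conventions above; `mask_to_surface()`,
  `hd95()`/`asd()` and `detect_endpoints()` raise errors.
* Curves: < 2 control points, coincident consecutive points, zero arc
  length, tube exiting the grid (error names the axis), and r + t exceeding
  the minimum bending radius (self-intersection) are all rejected.
* Constant volumes cannot be z-normalized (zero variance) and non-positive
  intensities cannot be bias-flattened.
* All stochastic stages (phantom noise, augmentation, shuffling, weight
  init) draw from seeds; the CLI chain is byte-deterministic, and training
  twice with one seed gives bit-identical histories on CPU.

# Known limitations

* The Dijkstra centerline is a discrete approximation of the Voronoi
  medial axis; on flat medial regions (elliptical sections) the inscribed
  radius is accurate only to about one voxel.
* d_MIS inherits half-voxel uncertainty from surface placement; d_CE is
  the more accurate of the two diameters here, as in the original study.
* The Hough radius range and the axial-rotation interpretation are
  documented guesses where the protocol is silent.
* Toy-scale training on phantoms demonstrates the learning machinery; it
  says nothing about multicenter clinical Dice scores.
* Only axis-aligned (direction ≈ identity up to sign) NIfTI volumes are
  supported; reorient externally first.
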