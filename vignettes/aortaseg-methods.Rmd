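---
title: "Methods: cascaded attention U-Net segmentation and morphometry of the aorta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded attention U-Net segmentation and morphometry of the aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Abdominal aortic aneurysms (AAA) are monitored by CT. On a contrast-enhanced
angiogram (CTA) the blood lumen is bright and easy to delineate, but the
clinically critical structures around it — the vessel wall and the
intraluminal thrombus (ILT) that lines most aneurysms — have soft-tissue
radio-densities and defeat intensity-based methods. On non-contrast CT even
the lumen is nearly iso-intense with its surroundings. `aortaseg` implements
a fully automatic two-stage segmentation pipeline for both settings,
together with the morphometric measurements (diameters, areas, volumes,
centerlines, diameter profiles) that drive aneurysm surveillance, and the
agreement statistics used to validate them.

Because clinical cohorts are ethics-restricted, the package ships a
first-class synthetic phantom generator with *analytic* ground truth; every
quantitative claim made by the test suite is made against phantoms whose
geometry is known in closed form.

# The segmentation cascade

The pipeline mirrors the coarse-to-fine design common in volumetric medical
segmentation:

1. **ROI detection.** The volume is intensity-normalized, resampled to
   isotropic voxels and down-sampled by a factor of 3.2 per axis
   (512 × 512 in-plane becomes 160 × 160). A small 2-class network segments
   "aorta vs background" on this cheap grid.
2. **Bounding boxes.** The thresholded foreground probability (default 0.5)
   is cleaned by connected-component analysis (components under 1 cm³ are
   noise) and converted to boxes. A contrast volume yields two boxes —
   thoracic and descending/abdominal — while a non-contrast volume (which
   covers only the abdomen) yields one.
3. **High-resolution segmentation.** Each box, padded by 10 voxels and
   mapped back through the down-sampling factor, crops the full-resolution
   volume; a 3-class network (background / lumen / wall+ILT) segments each
   crop, and the crops are stitched back, resolving overlaps by maximum
   class probability.

**Thoracic/abdominal split rule.** How exactly the two contrast boxes are
derived is a genuinely open design point; we use geometry alone: scanning
axial slices from superior to inferior, the aorta shows *two* in-plane
components wherever the ascending and descending limbs coexist (below the
arch, above the root). The thoracic box ends at the most inferior such
slice, the abdominal box starts there, and both receive a 20 mm craniocaudal
margin so the regions overlap slightly. If no slice shows two components
(no arch in the field of view) a single abdominal box is returned with a
message.

# The network

`fit_unet()` trains a 3D encoder–decoder with skip connections. Each
resolution level applies two 3 × 3 × 3 convolutions with ReLU; the encoder
halves resolution by 2 × 2 × 2 max pooling while doubling channels, and the
decoder mirrors this with nearest-neighbour upsampling followed by a 1 × 1 × 1
projection. The final 1 × 1 × 1 layer produces per-voxel class scores
normalized to a probability simplex — classes are mutually exclusive, so
hard masks are obtained by per-voxel argmax rather than per-channel
thresholding.

**Attention gates.** Before concatenation, each skip connection passes
through an additive attention gate: with skip features $x$ and the gating
signal $g$ from the coarser scale (upsampled and projected to the same
channel count),

$$\alpha = \sigma\!\big(\psi^\top \mathrm{ReLU}(W_x x + W_g g + b_g) + b_\psi\big),
\qquad \hat{x} = \alpha \odot x,$$

with $\alpha \in [0,1]$ one coefficient per voxel. A per-channel variant
("multidimensional" coefficients) is available via
`attention_per_channel = TRUE`; the per-voxel form is the default because on
the phantom task the two are indistinguishable and the per-voxel form has
fewer parameters. The gate biases are initialized so that $\alpha \approx
0.73$, i.e. the gate starts nearly open and learns to suppress. With
`attention = FALSE` the architecture reduces exactly to the plain 3D U-Net
baseline (verified in the tests by forcing $\alpha = 1$).

**Loss.** Training minimizes a soft Dice loss averaged over the
non-background classes,

$$L = 1 - \frac{1}{C-1}\sum_{c=1}^{C-1}
\frac{2\sum_i p_{ic}\,g_{ic} + \varepsilon}{\sum_i p_{ic} + \sum_i g_{ic} + \varepsilon},$$

with $\varepsilon = 10^{-5}$; a class absent from both prediction and target
therefore contributes zero loss (Dice 1 for two empty sets). On hard one-hot
inputs the loss equals one minus the mean Dice score, which the tests
cross-check against the independent `dice_score()` implementation.

**Optimization and implementation.** The convolutions are implemented as
im2col + GEMM in compiled code with hand-written backpropagation (verified
against central finite differences on every parameter tensor), and Adam
(learning rate 10⁻³) updates the weights. The reference architecture
configuration is unpublished, so channel counts, depth and epochs are free
parameters: we default to depth 3 and 8 base channels, which is the scale at
which a single CPU trains in minutes. Training samples random patches
(default 32³, foreground-biased) and applies online random affine
augmentation: rotation uniform on [0°, 15°] about a random axis, isotropic
scaling on [0.7, 1.3], translation within ±10 % of the field of view (the
translation range is not specified anywhere and is our choice). All
randomness — initialization, patch draws, augmentation — derives from the
config seed, making training runs bit-reproducible.

# Offline augmentation

Cohorts are expanded 10:1 by "divergence transformations": sums of
Gaussian-windowed radial displacement bumps

$$u(x) = \sum_k m_k \frac{x - c_k}{\lVert x - c_k \rVert}
\exp\!\left(-\frac{\lVert x - c_k\rVert^2}{2\sigma_k^2}\right),$$

applied by backward warping — positive magnitudes locally dilate the
anatomy, negative ones contract it. The exact non-linear warp family used in
the original setting is not disclosed; this family realizes locally
divergent/convergent deformations at predefined locations with three
parameters per control point, which is the property that matters. Control
points (default 3 per copy) are sampled inside the aorta mask so the
deformation targets the structure of interest; magnitudes default to
±5 mm and windows to σ = 15 mm. The original images are retained, so 75
cases become 825 sets (75 × 11) and a 50-case training split becomes 550 —
matching the arithmetic of the 10:1 protocol with originals included, which
is the only reading consistent with both counts. Image and mask are warped
by the same field (trilinear vs nearest interpolation), and every augmented
copy records its seed and warp parameters.

# The phantom generator

`generate_phantom()` builds a paired contrast / non-contrast CT-like volume
from an analytic description: an interpolating cubic spline centerline
(arc length by dense polyline summation, 0.1 mm tolerance), a
piecewise-linear lumen radius profile with an aneurysmal bulge, a constant
wall thickness, and a crescentic thrombus occupying an angular fraction of
the bulge. Voxels are classified by their centre point (no anti-aliasing):
lumen within the local radius, wall/thrombus within radius + wall. The
crescent thickens the wall *inward* with depth
$0.7\,(r(s) - r_\mathrm{tube})$ at its centre, tapered cosinusoidally to
zero at its angular edges — so the thrombus appears exactly where the
aneurysm dilates, the outer wall stays circular, and the lumen is eaten into
from one side, the typical appearance of an eccentric ILT. None of this is
claimed to match any individual patient; it is the minimal model carrying
the features the pipeline must recover.

Defaults emulate routine acquisition: 512 × 512 axial matrices, 1.25 mm
slices for the contrast volume and an independently rasterized 2.5 mm-slice
non-contrast rendition. Intensities are "HU-like" free parameters (no
quantitative cohort statistics are available): background 30, wall 60,
thrombus 40, contrast lumen 300, non-contrast lumen 45, Gaussian noise
SD 15 — chosen so that the non-contrast lumen sits within 2 noise SDs of
background (nearly invisible) while the contrast lumen sits more than 10
SDs away, the documented invariants. Labels are a deterministic function of
the geometry; the seed controls only noise and cohort draws.

Cohorts randomize anatomy from documented ranges (baseline radius 8–12 mm,
bulge radius 15–27 mm — AAA diameters of 3–5.4 cm, wall 1.5–3 mm, thrombus
fraction 0.2–0.8, lateral wiggle up to 6 mm), clipped so the geometry fits
the grid.

**Discretization error and the sub-voxel oracle.** Because voxels are
classified by centre, a voxel mask over- or under-counts volumes near the
surface. Rather than anti-alias, `oracle_volumes()` re-rasterizes with each
voxel subdivided 5³ times, quantifying that error; the recovery tests
require the voxel-count volumes to agree with this oracle within 3 %, and
measured diameters to agree with the analytic profile within one in-plane
voxel.

**What the phantom does not emulate:** beam hardening, streaks, organs and
other soft-tissue context, branch vessels, calcification, partial-volume
blur. Passing the phantom suite therefore demonstrates that the pipeline's
machinery (geometry, learning, measurement) is correct — not that the
shipped defaults reach clinical accuracy on patient data, which would
require training at scale on a real cohort.

# Morphometry definitions

- **Axial AP / transverse diameters** are caliper extents of the largest
  in-plane connected component along the fixed anatomical axes (y = AP,
  x = transverse) — the clinical axial caliper. In oblique planes
  anatomical axes are undefined, so **centerline-orthogonal diameters** use
  the maximum Feret diameter of the component containing the centerline
  point. Both definitions are deliberate: the axial caliper is *extent*,
  not Feret.
- **Three-slice protocol**: AP + transverse at the maximum-AP slice and at
  the slices 1 cm above and below (nearest slice by spacing); a mask
  shorter than the span yields a truncated, flagged result.
- **Centerlines** come from distance-ordered homotopic thinning: voxels are
  deleted in increasing distance-to-background order whenever deletion
  preserves topology (the standard (26, 6) simple-point characterization)
  and the voxel is not a curve endpoint; the skeleton is then pruned to its
  longest geodesic path (ties broken by lexicographic endpoint order),
  ordered superior → inferior, in world mm. The published description cites
  an external thinning implementation without parameters; distance ordering
  is the choice that keeps the curve medial.
- **Centerline deviation** is the mean closest-point distance. The
  published description is directional; we symmetrize by averaging both
  directions and also report the directed values as attributes. The
  **Hausdorff distance** is the maximum of the two directed maxima and
  provably upper-bounds the mean deviation.
- **Diameter profiles** sample planes orthogonal to the
  moving-average-smoothed centerline (5-point window, 1 mm default step);
  profile agreement is RMSE plus mean percentage difference
  $\operatorname{mean}(|d_1-d_2| / \operatorname{mean}(d_1,d_2)) \times 100$
  on the overlapping arc range after linear interpolation.
- **Agreement statistics**: Bland-Altman bias with 95 % CI
  ($\pm 1.96\,SD/\sqrt n$) and limits of agreement ($\pm 1.96\,SD$),
  Spearman rank correlation, and the intraclass correlation coefficient.
  The ICC variant is not specified in the source description; we compute
  ICC(A,1) — two-way, absolute agreement, single rater — and label it as
  such. The %CV is the root mean square over pairs of each pair's SD over
  its mean (the within-subject RMS convention; the alternative
  SD-of-differences convention is not used).

# Numerical choices and degenerate inputs

- Coordinates: 0-based voxel indices, half-open boxes, world = origin +
  index · spacing; +z is superior.
- Down-sampled dimensions round half away from zero, so 512/3.2 = 160
  exactly and the rule is deterministic.
- The isotropic working resolution defaults to 1 mm (the source pipeline
  never states its target); interpolation is trilinear for images and
  nearest-neighbour for masks, so resampling can never invent labels.
- The intensity window defaults to (−100, 400) HU-like units; it is a
  config parameter because no normalization is specified anywhere.
- Soft-Dice ε = 10⁻⁵; two empty sets have Dice 1.
- Empty detections, geometry mismatches, too-small grids and sub-minimum
  cohort sizes raise typed errors naming the offending stage; masks with
  several components use the largest with a message.
- Feret diameters are computed on the convex hull of component pixel
  centres plus one pixel, approximating the caliper width of the pixel
  squares.

# Problem sizes used by the tests

The shipped test-suite and acceptance script run entirely on synthetic
phantoms sized for a single CPU: 64³–128³ grids at 1.25–2 mm voxels,
cohorts of 9–75 cases, and a smoke training run of a depth-3 / 8-channel
attention U-Net on eight 64³ phantoms for at most 30 epochs (16 in the
shipped configuration, which passes the held-out Dice ≥ 0.8 bar with
margin). These sizes are the package's chosen desk-scale study conditions;
the architecture scales to clinical grids by raising `depth`,
`base_channels` and `patch_size` in `unet_config()`.

# Known limitations

- The hand-rolled training loop is single-threaded CPU code; it is meant
  for reproducible desk-scale experiments, not clinical-scale training.
- The thoracic/abdominal split rule assumes the arch is in the field of
  view when two boxes are requested.
- Centerline endpoints retract by roughly one lumen radius relative to the
  analytic curve (thinning cannot extend beyond the mask), so diameter
  profiles do not cover the extreme ends of the vessel.
- The phantom's non-contrast rendition keeps the wall faintly visible
  (wall 60 vs background 30); real non-contrast delineation is harder.
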