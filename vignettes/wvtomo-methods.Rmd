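---
title: "Methods: multicolor block-face tomography reconstruction, planning and quantification"
author: "wvtomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicolor block-face tomography reconstruction, planning and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wvtomo)
```

# The imaging problem

Wide-field large-volume tomography (WVT) images a resin-embedded whole brain
by alternating mosaic optical imaging of the block face with mechanical
sectioning. Three fluorescence channels are acquired simultaneously: blue
carries the DAPI counterstain applied to the freshly cut face in real time
(cytoarchitecture for anatomical annotation), while green and red carry the
fluorophores of interest (here: projection inputs and a genetically labelled
cell type). Each mosaic field of view (FOV) is 1,800 × 1,800 px at
0.32 µm/px, i.e. 576 × 576 µm², with a 5 µm overlap between adjacent FOVs
and a 2 µm axial step.

Two optical facts shape the whole pipeline:

* **Axial chromatic aberration** of the illumination path puts the blue
  illumination plane about 10 µm below the green/red one.
* **Real-time counterstaining is surface-confined**: DAPI only penetrates a
  few micrometres of the fresh face, and its crosstalk into the green
  channel decays to the noise floor at an imaging depth of 4 µm.

`wvtomo` re-implements the computational side of this instrument —
reconstruction, channel registration, contour-driven acquisition planning,
acquisition accounting, and soma co-location/region quantification — and
ships a synthetic phantom-brain generator that exercises every module with
known ground truth.

# Detection-plane geometry

With the green/red detection planes (GDP/RDP) held 4 µm below the sample
surface (below the crosstalk-free depth), a *conjugated* blue channel (its
detection plane conjugate to its illumination plane) would sit at
`gdp + separation` = 14 µm — where the surface-confined counterstain leaves
nothing to detect. The *optimized* scheme breaks the blue conjugation and
raises the blue detection plane by the crosstalk-free depth, to the sample
surface:

```{r geometry}
g <- OpticalGeometry(axialChromaticSeparation = 10, gdpOffset = 4)
bdpOffset(computeDetectionPlanes(g, "conjugated"))
bdpOffset(computeDetectionPlanes(g, "optimized"))
```

A negative computed depth (plane above the block face) is flagged
(`bdpOutOfSample`) rather than raised: it is a physically meaningful
configuration the operator may want to inspect.

# Three-phase reconstruction

Each FOV is illuminated with a fringe pattern at phases 0, π/2 and π. For
raws $I_k = S\,(1 + m\cos(\theta + k\pi/2))/2$ the optically sectioned (SIM)
image is demodulated pixelwise as

$$I_{\mathrm{SIM}} = \tfrac12\sqrt{(I_0 - I_2)^2 + (2I_1 - I_0 - I_2)^2}
  = \tfrac{mS}{2},$$

independent of the local fringe phase $\theta$, and with complete rejection
of any unmodulated (out-of-focus) term. The demodulation formula is chosen
as the unique three-step closed form that is exact for a π/2 phase step; its
phase independence and DC rejection are asserted to 10⁻⁹ relative error in
the tests. The wide-field (WF) image superposes the three raws as a **sum**
(preserving photon-count semantics; a mean is available for display). In the
optimized scheme the blue detection plane is essentially unmodulated, so the
blue channel uses WF reconstruction while green/red use SIM — the default
per-channel scheme of `reconstructFov()`. Saturated raw pixels are
propagated and flagged in a mask, never repaired; SIM output is non-negative
by construction so no clipping is applied. No inter-tile intensity
normalization is performed.

The generator's `modulateSim()` models the DMD's binary fringes as sinusoids
at the sample (the objective passes only the fundamental) and can curve the
illumination plane: with `curvature > 0` the out-of-focus term acquires a
residual modulation growing quadratically towards the field edge, which
reproduces the observed edge-dominant counterstain crosstalk; it is emulated
but deliberately not corrected.

# Lateral chromatic registration

The green channel is fixed; blue and red are corrected by a lateral
similarity transform (translation, rotation and isotropic scale about the
image centre — the channels share one optical axis) that maximizes the
normalized cross-correlation with the fixed image. The search is a coarse
grid over rotation × scale, with the best translation per candidate taken
from the FFT cross-correlation peak, followed by Nelder–Mead refinement of
all four parameters; it is derivative-free and robust on the smooth
correlation surfaces involved. Interpolation is bilinear; an achieved
correlation below 0.2 raises a registration failure. Estimated parameters
are serialized to JSON and reused for a whole dataset, re-estimated only
after optical re-configuration.

Residual co-location error is measured as the sub-pixel displacement of the
windowed correlation peak (128 px windows by default; the window size is a
package choice, exposed as a parameter) at the FOV centre and four corners.
The displacement search is a direct normalized cross-correlation over
integer shifts with separable quadratic sub-pixel refinement — a circular
FFT correlation would bias weakly structured corner windows toward zero
shift through wrap-around. When measuring on *warped* synthetic images, the
resampling leaves a zero-filled dead zone along the borders; the probe
positions accept an extra inset (`borderPx`) so windows stay on real
content (real two-channel acquisitions have content everywhere, so the
default inset is zero). On synthetic targets with injected misalignments inside the
recovery envelope (|shift| ≤ 10 px, |rotation| ≤ 1°, |scale − 1| ≤ 0.01) the
estimate-apply round trip leaves residuals well below one pixel (0.32 µm),
the instrument's published post-registration bound.

One synthetic-data subtlety: a *pure* concentric-ring target is rotationally
symmetric, so its rotation component would be unidentifiable. The package's
`makeRingTarget()` therefore overlays a fixed, deterministic golden-angle
spiral of spots on the rings (the physical calibration slide likewise
carries non-ring features).

# Contour recognition and minimum-region planning

The coronal DAPI preview (downsampled to 1.68 µm/px by area-weighted
resampling; the 0.32 → 1.68 factor of 5.25 is not integer) passes through a
classical morphology chain: median filter (5 px), threshold, opening,
connected-component filtering, hole filling. Defaults and their rationale:

* **Threshold**: Otsu on the median-filtered image. The real-time
  counterstain yields uniform per-layer contrast, which keeps Otsu stable; a
  fixed threshold is available as a fallback.
* **Opening**: disc of radius 3 px (≈ 10 µm) removes sectioning debris while
  preserving the cortical boundary. A disc rounds ideal rectangle corners by
  less than its radius; a box element (exact on rectangles) is available.
* **Fragment removal**: components other than the largest are dropped when
  smaller than `minFragmentArea` (500 px²) or when their centroid lies
  farther from the image centre than `fragmentDistanceLimit`; the default
  limit is derived per image as the largest component's bounding radius
  + 500 µm, a conservative reading of "far from the image centre".
* **Hole filling**: full flood-fill of the border complement, so ventricles
  of any size are filled.

When nothing survives, an explicitly flagged empty contour is returned and
the caller reuses the previous imaging region for that layer.

The minimum imaging region expands the contour's circumscribed rectangle by
a 288 µm margin (half the FOV) on all four sides and rounds it up to the
smallest run of columns and rows of the **fixed mosaic lattice** (stride
= 576 − 5 = 571 µm, origin constant for the whole dataset so that all layers
auto-register). Coverage arithmetic uses 0-based lattice indices and
pixel-centre coordinates.

Two desk-scale design points deserve a note:

* The margin exists to absorb both recognition error and the growth of the
  cross-section between consecutive layers (the region for layer *k+1* is
  planned from the contour of layer *k*). The meaningful coverage guarantees
  — both asserted in the tests — are that each planned region covers (a) the
  recognized rectangle dilated by the margin and (b) the *actual* tissue of
  the layer it images. A guarantee of covering the next layer's tissue
  dilated by the full margin would be unsatisfiable whenever the section
  grows, since the margin is exactly the growth allowance.
* Layer 1 has no preceding contour. The package plans it from its own
  contour, standing in for the operator-configured initial region around the
  visible first face; a full-image fallback applies when recognition fails.
  At production scale (~10⁴ layers) this choice is irrelevant; at desk scale
  (3–10 layers) a full-frame first layer would dominate the totals and
  invert the with/without-recognition comparison.

# Acquisition accounting

`tileSizeMb()`, `datasetSizeTb()`, `imagingTimeH()` and
`exposureReduction()` reproduce the acquisition arithmetic: binary units
(MB = 2²⁰ B, TB = 2⁴⁰ B) are used because only they are internally
consistent with the published tile and dataset sizes (1,800² × 16 bit
= 6.18 MB; decimal units sit behind a flag); dataset sizes count one
reconstructed image per mosaic per channel (the three phase raws are
consumed by reconstruction, not archived); imaging time multiplies the
*per-channel* mosaic count by the all-inclusive 342.5 ms per mosaic, since
the channels are simultaneous. `summarizePlan()` reports the mosaic
reduction under both aggregation modes — ratio of totals and mean of
per-layer ratios — because they differ whenever layer sizes vary and the
published "37 %" average is an over-brains aggregate that cannot be pinned
to either from the printed per-condition averages (whose ratio is 36.4 %).

# Soma co-location and region quantification

Soma detection (`detectSomas()`) is deliberately plain plumbing standing in
for the external localization tool used on the instrument: block-wise
(512³ voxels at 1 × 1 × 2 µm with a 16-voxel halo) Gaussian smoothing at the
soma scale (σ = 4 µm), strict local maxima above median + 6 × MAD, and
duplicate merging within 3 µm across halos.

Co-location follows the published rule — two somas are one doubly labelled
neuron when their distance is **strictly below 1 µm** — made one-to-one by
mutual-nearest-neighbour matching (each soma must be the other's nearest
counterpart), which prevents a single soma from being claimed twice; the
distance is 3D Euclidean in micrometres, anisotropy having been absorbed at
detection. The manual-proofreading step of the original workflow is replaced
by a CSV review export (`exportReviewCandidates()`).

Region counting assigns each soma the label of its containing atlas voxel
(floor-to-voxel; boundary coordinates deterministically belong to the upper
voxel), optionally rolled up from sub-regions to parent regions; somas on
background are counted in a flagged "unassigned" bin so proportions always
total 100 %. Cross-brain aggregation reports mean ± s.e.m. (sd/√n), with a
missing region treated as 0 % for that brain and n = 1 flagged. Deformable
atlas registration is out of scope: synthetic atlases are generated
pre-aligned in the data frame.

# The phantom generator and what it does (not) show

`phantomSpec()` fixes the study conditions of all synthetic experiments; its
defaults are: 5 coronal layers at 1.68 µm/px (1,536 px frame), a
superellipse outline with a low-order angular wobble whose semi-axes taper
from ~100 to 420 × 300 µm along the axis, an elliptical ventricle (18 % of
the section axes) that recognition must fill, 3 peripheral sectioning
fragments of 30–80 µm placed beyond the fragment-distance limit, ~2,000
nuclei/mm² of Gaussian speckle over a diffuse tissue signal, Gaussian read
noise of 50 counts (Poisson shot noise optional), 10,000 green and 9,000 red
somas in a 200 µm slab, a planted co-location fraction of 0.22 % (the scale
of the published biological result) realized as a binomial draw and
duplicated within 0.8 µm, distractor reds kept ≥ 2 µm from any green soma,
and a 60/30/10 planted distribution over three parent regions (each split
into two sub-regions) of an 8 µm-voxel atlas. The taper is strong enough
that planned extents cross mosaic-stride boundaries; with a weaker taper the
571 µm lattice quantization would hide the shrinkage entirely at desk scale.
One seed fixes all randomness, and the generator restores the caller's RNG
state. Atlas region cuts snap to atlas-voxel boundaries so that a soma's
generative region always agrees with its containing voxel's label; the
ground-truth region of each soma is recorded from its realized coordinate.

What passing tests show: the demodulation, registration search, morphology
chain, lattice arithmetic, pairing rule and counting are correct on data
whose generative model is known exactly. What they do not show: performance
on real tissue — scattering, uneven staining, deformation, densely packed
or dim somas, real ventricle shapes — nor the instrument's specific
published percentages, resolutions (0.48/0.53/0.84 µm laterally) or its
pre-registration chromatic offsets, all of which depend on the hardware and
the brains themselves and are deliberately not acceptance surfaces here.

# Numerical choices and problem sizes

Tolerances: SIM amplitude recovery is asserted at 1e-9 relative error
(float demodulation of exact sinusoids); Gaussian FWHM fits recover the
generating σ to 1e-6 on noise-free profiles and are compared within 2–5 % on
sampled/noisy beads; registration recovery is asserted at ≤ 0.1 px
(parameters) and ≤ 1 px (residual co-location). Degenerate inputs have
defined behaviour throughout: flat profiles, structureless images, empty
volumes and empty soma sets raise classed errors or return flagged empties
rather than guessing.

Test problem sizes are desk-scale by design: 192 px ring targets (20 random
misalignment seeds), 50 single-layer phantoms at 1,536 px plus one 6-layer
tapered brain for the planner, 10 phantom seeds at 10,000/9,000 somas for
quantification, 128³-voxel blocks for detection. These sizes were chosen so
the whole suite exercises every module end to end at full parameter
fidelity (FOV, overlap, margin, voxel sizes are always the instrument's)
while the statistics (binomial co-location error, IoU, residuals) remain
sharp enough to detect implementation faults.

# Known limitations

* The SIM path implements optical sectioning only — no frequency-domain
  super-resolution and no correction of illumination field curvature.
* Registration is lateral-similarity only; axial channel alignment is the
  optics model's job, and deformable registration is out of scope.
* `detectSomas()` is intentionally simple plumbing; it is not a
  re-implementation of the external localization tool and will undercount
  in dense or dim regions of real data.
* The phantom's nuclei/tissue contrast is clean by construction; Otsu's
  stability on marginal real staining is not established here.
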