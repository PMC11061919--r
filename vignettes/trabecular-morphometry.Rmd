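---
title: "Trabecular bone morphometry with trabmorph: models, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular bone morphometry with trabmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`trabmorph` measures the 3D microarchitecture of trabecular (spongy) bone in
CT volumes. The input is a grayscale volume with isotropic voxel spacing plus
a binary volume of interest (VOI) that delineates the trabecular compartment
(cortical bone already excluded). The pipeline is

1. **Segmentation** of bone from marrow — either iterative homogeneity-driven
   *automated region growing* (ARG), or Otsu thresholding for
   high-contrast-to-noise data such as micro-CT;
2. **Skeletonization** of the bone phase by topology-preserving 3D thinning;
3. **Local maps and counts** yielding ten numbers per volume: BVTV (bone
   volume fraction), Tb.Th / Tb.Sp / Tb.Sc (trabecular thickness, edge-to-edge
   separation, midline-to-midline spacing, all in mm) with their intra-volume
   standard deviations s(Tb.Th), s(Tb.Sp), s(Tb.Sc), the skeleton node and
   terminus densities Tb.Nd and Tb.Tm (per mm^3), and the contrast-to-noise
   ratio CNR;
4. **Method agreement statistics** for paired device studies: Pearson
   correlations with Fisher-z confidence intervals and R^2, Bland–Altman bias
   and 95% limits of agreement with a proportional-bias regression, and
   paired t-tests with confidence intervals of the difference.

A synthetic phantom generator with analytic ground truth and a scanner
degradation simulator make the whole chain testable without scanner data.

# The ARG segmentation model

ARG treats segmentation as a two-region competition. Bone seeds are the
brightest voxels of the VOI (top 2% by default — bone is the bright minority
phase) and background seeds the darkest 20%. The regions then grow
alternately, bone first. A frontier voxel joins a region when its intensity
lies within `t * sd(VOI)` of the *running region mean*, which is updated
incrementally as voxels accrete; within a turn the frontier is processed as a
FIFO queue in ascending linear-index order, so the algorithm is fully
deterministic. Voxels claimed by neither region once growth stalls are
assigned to the region with the nearer mean (ties to bone, matching the
bone-first turn order).

The homogeneity threshold `t` is swept over a schedule of 20 values,
geometrically spaced from 0.05 to 2.0 in units of the VOI intensity SD: the
sweep starts deliberately under-segmenting and ends over-inclusive. Each
candidate partition is scored by region homogeneity,

```
h(region) = 1 - sd(intensity | region) / sd(intensity | VOI),   clipped to [0, 1]
```

and the combined score is the unweighted mean of the bone and background
scores; the first threshold attaining the maximum wins. Two conventions here
were genuinely open and are the package's own choices:

* **Scores are computed on the final partition** (after the nearest-mean
  assignment), not on the grown regions. Scoring the grown regions would
  always select the smallest threshold — seed sets are maximally homogeneous
  by construction — which contradicts the intent of picking the most useful
  segmentation. An empty region scores 0 so the sweep has a total order.
* **Mean combination.** Whether "both regions reached the highest
  homogeneity" means the mean, sum, or minimum of the two scores is not
  derivable; the mean is used (the sum has the same argmax, the minimum
  degenerates to whichever region is noisier).

The `Segmentation` object retains both views — `bone_grown` (at `t -> 0` it
is exactly the seed set) and `bone` (the final partition) — plus the full
homogeneity trace for inspection or CSV export.

Otsu thresholding follows the textbook between-class-variance criterion over
an equal-width histogram (256 bins by default) restricted to the VOI, with
ties broken toward the lower threshold. On noiseless two-level volumes ARG
and Otsu agree voxel for voxel, which the test suite asserts.

# Morphometric conventions

**Local thickness** uses the maximal-inscribed-sphere definition: the value
at voxel x is the diameter of the largest sphere that fits inside the
structure and contains x. It is computed from an exact squared Euclidean
distance transform (separable lower-envelope algorithm), reduced to the
distance ridge, with spheres painted in decreasing radius order. The sphere
radius convention is `r = EDT - 0.5` voxels — the distance to the phase
*boundary* rather than to the nearest background voxel centre — so an
isolated voxel measures exactly one voxel and a slab of k voxels measures
exactly k voxels when k is odd. For even k the maximal sphere is centred
between voxel centres, which a centre-sampled map cannot represent: even
widths measure k − 1 voxels. Accuracy is therefore one voxel, exact for odd
widths. This quantization matters below.

**Tb.Th** is the mean of the thickness map over bone voxels; **Tb.Sp** is
the thickness map of the marrow phase (complement of bone) sampled over VOI
background voxels; **Tb.Sc** is the thickness map of the complement of the
*skeleton*, sampled over the same background voxels — a constructive reading
of "distance between midlines". Because the skeleton is a subset of bone,
`Tb.Sc >= Tb.Sp` holds on every input by monotonicity of inscribed spheres
under set inclusion. The dispersions s(·) are sample standard deviations
over the same supports.

**Boundary convention.** Structures are assumed to continue beyond the
volume faces: the distance transform never treats out-of-grid voxels as
background, and the thinning never deletes a voxel one-sidedly against a
face (nor counts out-of-grid voxels as background in its topology tests).
Without this, plates and rods cut by the VOI erode from the artificial cut
faces and the background maps blow up in half-open boundary gaps. The same
convention makes "crop to the VOI bounding box, then analyze" identical to
"analyze with the mask", which `analyze()` exploits by always cropping first.

**Skeletonization** is sequential 6-directional thinning deleting only
*simple points* (one 26-connected foreground component in the
26-neighbourhood and one 6-connected background component in the
18-neighbourhood touching the centre), with curve endpoints (at most one
neighbour) preserved. Connected-component counts are preserved exactly;
one-voxel-thick plates are non-simple in their interior and survive as
medial surfaces, so plate-like bone keeps a midplane rather than collapsing
to a curve. No branch pruning is applied: small surface irregularities do
register as termini, which is a known sensitivity of terminus counting at
high resolution.

**Tb.Nd** counts 26-connected *clusters* of skeleton voxels with at least
three skeleton neighbours (a junction of thick rods yields one cluster, not
one count per voxel); **Tb.Tm** counts voxels with exactly one neighbour.
Both are divided by the VOI volume in mm^3. Axis-aligned corners of digital
loops register as junction clusters under 26-adjacency — an honest property
of the definition that the unit tests document.

**CNR** is `(mean(I | skeleton) - mean(I | background)) / sd(I | background)`
with background defaulting to VOI minus bone (marrow). A noise-free volume
has zero background SD; `analyze()` reports `Inf` in that case rather than
failing, while the low-level `cnr()` keeps the strict error contract.

# The phantom generator and what it emulates

Phantoms are two-intensity volumes (defaults: bone 1000, marrow 100 —
arbitrary units; every downstream measure is affine-invariant) built from
three geometries:

* `plate_stack` — parallel plates normal to z; truth BVTV = width/pitch,
  Tb.Th = width, Tb.Sp = pitch − width, Tb.Sc = pitch;
* `rod_lattice` — rods along z on a square grid; truth BVTV = pi r^2 / pitch^2;
* `mixed` — the union of rod families along x, y and z: a connected lattice
  with genuine skeleton junctions, the closest of the three to a trabecular
  network. Its volume fraction is taken from the generated grid (the
  three-family union has no closed form worth defending).

Plates are centred on pitch multiples so that a volume spanning a whole
number of pitches cuts plate mid-planes at its faces and every marrow gap is
interior; rod axes are offset by half a pitch so rods and their junctions
sit away from the faces, where medial structure would otherwise be
truncated by the cut.

The degradation chain emulates what a scanner does to the fine structure:
isotropic Gaussian PSF blur (reflective boundaries, intensity-conserving),
resampling to the device voxel size (block mean for integer ratios — the
same operation as the 16.4-to-32.8 um micro-CT reduction — trilinear
otherwise), and additive Gaussian noise. The noise field is correlated with
the same PSF on the device grid before rescaling to the calibrated SD,
because reconstruction kernels correlate CT noise; white per-voxel noise
produces unrealistically ragged boundaries on 2–3-voxel structures. The PSF
width is 0.6 x the target voxel size, and the noise SD is calibrated so the
predicted CNR against nearly bone-free marrow (occupancy < 5%) hits the
device anchors: 12.57 at 32.8 um, 6.98 at 61 um, 6.68 at 82 um. Calibrating
against *pure* marrow matters: at coarse voxels the complement of the truth
mask is contaminated by partial-volume voxels whose spread is structure, not
noise, and would make the coarse anchors unreachable.

The cohort generator draws element widths from U(0.12, 0.20) mm and pitches
from U(0.6, 0.9) mm — distal-radius trabeculae are 0.1–0.2 mm thick, and
these ranges reproduce volume fractions of roughly 0.05–0.25. The
resolution-trend study uses a single mixed lattice with 0.18 mm elements at
1.0 mm pitch, matching the reference micro-CT measurements of thickness and
spacing in the validation study this package re-implements, at 16.4 um base
spacing (3 mm extent, 183^3 voxels), segmented with ARG at every resolution
(the algorithm the original study applied to its clinical-resolution data).
Problem sizes (128^3 for segmentation recovery, 1.8 mm specimens for the
23-member cohort) were chosen so the full suite runs in minutes on one core
while keeping several pitches of structure per volume.

What the phantoms deliberately do **not** emulate: real plate-rod topology
(no Voronoi-like microarchitecture), beam hardening, ring artifacts, or the
anisotropic, spatially varying PSF and noise spectra of real scanners.
Passing phantom tests therefore demonstrates correctness of the algorithms
under controlled geometry, not clinical equivalence on real bone.

# Validation statistics

`pearson_ci()` computes the product-moment correlation with the Fisher-z
interval `tanh(atanh(r) +/- z_{1-a/2} / sqrt(n-3))` and the t-distributed
p-value for r = 0; `pearson_ci_from_r()` exposes the same closed form from
(r, n) alone, which is exactly what is needed to check a printed correlation
table (for n = 23, r = 0.98 gives (0.95, 0.99) at two decimals). Bland–Altman
analysis uses the conventional 1.96 normal quantile for the 95% limits of
agreement and an OLS regression of differences on pair means for
proportional bias. The t-tests are *paired* — the same specimens are
measured on both devices — with explicit degenerate handling: all-zero
differences mean exact agreement (p = 1 by convention), constant nonzero
differences leave the statistic undefined (p = NA, CI collapsed to the
constant). Report rounding follows the two-decimal presentation of the
tables being reproduced.

# Numerical choices and degenerate inputs

* Volumes are 1-based `[x, y, z]` R arrays (column-major, x fastest);
  formats with other axis orders are rearranged on load.
* Spacing is carried in mm; the command-line interface accepts micrometres
  (`--spacing-um`) and converts. Anisotropic spacings are rejected unless an
  explicit override is given. NIfTI pixdims are 32-bit floats, so spacing
  comparisons use a 1e-6 relative tolerance.
* TIFF stores 32-bit floats in [0, 1]; `write_volume()` rescales and records
  scale + spacing in a JSON sidecar, and `read_volume()` inverts it. Foreign
  TIFFs are read with libtiff's [0, 1] normalization (all measures are
  invariant under that affine map) and require an explicit spacing.
* Block downsampling drops trailing voxels that do not fill a complete
  block rather than inventing padded intensities.
* Ties: Otsu breaks toward the lower threshold; ARG threshold selection
  takes the first maximum; voxels equidistant from both region means go to
  bone.
* An all-structure grid (e.g. Tb.Sp with empty bone) has no complement for
  the distance transform; the map falls back to the largest sphere inscribed
  in the grid box.
* The growth loop has a 10000-round safety cap; in practice a handful of
  rounds suffice because each turn exhausts its frontier queue.

# Known limitations

* **Thickness quantization.** Centre-sampled inscribed spheres measure even
  voxel widths one voxel low; structures two voxels wide measure one voxel.
  At clinical voxel sizes where trabeculae span 2–3 voxels this quantization
  can dominate resolution-driven thickening: in the resolution-trend study
  the measured Tb.Th dips at 61 um before rising at 82 um (present already in
  the noiseless limit), although BVTV shows the expected monotone
  partial-volume overestimation and Tb.Nd the expected monotone loss of
  detected junctions. The validation
  study this package re-implements reports segmented thicknesses of 5–6
  voxels at 61 um — an effective scanner PSF about twice the voxel size,
  i.e. well above the 0.6 x voxel blur this simulation prescribes — which is
  why its thickness overestimation is monotone while the simulated one at
  0.6 x is not.
* **Unpruned skeletons.** Noise-driven surface bumps create short branches
  whose bases count as junction clusters and whose tips count as termini, so
  Tb.Nd and Tb.Tm carry an upward noise sensitivity at low CNR; terminus
  sensitivity is a documented property of the method in the source study
  too.
* The homogeneity functional's combined score is nearly flat over a wide
  threshold range on low-CNR volumes; selection among near-tied partitions
  is stable (deterministic) but not robust to the score model itself.
* The ARG growth-monotonicity property (bone grown at larger t contains
  bone grown at smaller t) holds empirically on the tested fixtures but is
  not a theorem under incrementally updated means.
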