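---
title: "Voxel-based estimation of the craniofacial symmetry plane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based estimation of the craniofacial symmetry plane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symplane)
```

## The problem

The facial skeleton is nominally mirror-symmetric about the mid-sagittal
plane. Quantifying how symmetric a patient's skull actually is — and where
the best-fitting symmetry plane lies — matters for orthognathic surgical
planning: the plane is the reference against which left-right discrepancies
are measured and corrected. The classical clinical construction draws the
plane through manually identified cephalometric landmarks; a
landmark-independent alternative mirrors the bone surface and registers the
mirror image back onto the original. Both degrade on severely asymmetric
anatomy: landmark planes inherit the asymmetry of the landmarks themselves,
and surface registration is dragged toward large unilateral defects or
prominences.

`symplane` implements a voxel-based alternative. The bone mask of a CT scan
is treated as a binary occupancy function $v(x,y,z)$ on a voxel grid with
physical (mm) spacing. For a candidate plane, every foreground voxel center
is reflected across the plane; the voxel is *paired* if its reflection lands
inside an occupied voxel. The **symmetry ratio**

$$\mathrm{SR} = \frac{\#\{\text{paired foreground voxels}\}}{\#\{\text{foreground voxels}\}} \in [0, 1]$$

scores the candidate plane, and the **optimal symmetry plane** (OSP) is the
maximizer of SR over plane orientation and offset; the maximal value is the
**optimal symmetry ratio** (OSR). Because every occupied voxel votes, a few
voxels of streak artifact or a local defect cannot move the optimum much —
that robustness is the method's point.

## Plane parameterization and search

A plane is parameterized by spherical angles and an offset:
$n(\varphi, \theta) = (\sin\varphi\cos\theta,\ \sin\varphi\sin\theta,\ \cos\varphi)$,
with plane equation $n \cdot (x - a) + d = 0$ relative to an anchor $a$ (we
anchor at the foreground centroid, a concrete reading of "a plane through the
center of the skeleton"). The search domain is
$\varphi, \theta \in [0, \pi]$ — each orientation counted once — and
$d \in [-80, 80]$ mm (configurable).

SR is piecewise constant in $(\varphi, \theta, d)$: it only changes when
some reflected center crosses a voxel boundary. Gradients are therefore
useless and `find_osp()` is derivative-free and deterministic:

1. **Stage 1 — grid scan.** Orientations on a regular $3°$ grid (optionally
   restricted to a cone around the initial plane, which is the median plane
   of the foreground bounding box with normal along x), with $d$ at one-voxel
   steps clipped to the foreground's signed-distance span (planes outside the
   span pair nothing, so the clip cannot change the maximizer).

   A subtlety found during development and worth documenting: the SR peak in
   $d$ is *narrower than one voxel* — displacing the plane by half a voxel
   displaces reflections by a full voxel and unpairs a thin structure such as
   a cranial shell. A one-voxel $d$-grid can therefore skip the true basin
   entirely while some spurious secondary symmetry scores higher. Each
   orientation's best coarse $d$ is consequently polished by a halving line
   search (down to 0.1 mm) *before* orientations are compared.
2. **Stage 2 — multi-start pattern search.** The ten best stage-1 candidates
   are each refined by an iterated local pattern search over
   $(\varphi, \theta, d)$, halving steps until the angular step is below
   $0.1°$ and the $d$-step below $0.1$ mm; the best refined plane wins. The
   multi-start covers the analogous narrow-peak problem in orientation when
   the true normal falls between stage-1 grid points.

Ties in SR are broken by the smaller angle to the initial plane, then the
smaller $|d|$ — SR plateaus exist at finite resolution, and the tie-break
makes the reported plane unique and bit-reproducible. The full evaluation
trace can be kept (`keep_trace = TRUE`) and plotted for audit.

The pairing rule itself is voxel-center reflection plus half-open box
containment (equivalently, nearest-voxel rounding). Half-open boxes make
boundary cases deterministic: a reflected center on a shared face belongs to
exactly one voxel. Pairing is evaluated one-directionally (each foreground
voxel asks whether *its* reflection is occupied); the denominator is the
foreground count, matching the worked 2D example in which 30 of 41 shaded
pixels pair.

## Comparator planes

**Landmark plane (LSP).** The plane through the crista galli (CG), the
anterior nasal spine (ANS) and the midpoint of the left and right orbitale
(OrR, OrL). Collinear configurations are rejected with a distance-to-line
diagnostic. The midpoint makes the construction invariant to swapping the
two orbitale.

**Surface plane (SSP).** PCA initialization followed by mirror-ICP
refinement, run for a fixed ten outer iterations: split the surface cloud by
the current plane, mirror the smaller side across it, register the mirrored
points onto the other side with ICP, and update the plane from the ICP
rotation while keeping it anchored at the cloud centroid (the ICP
translation is discarded — the plane is assumed to pass through the center
of the skeleton, which is exactly the assumption that fails on severely
asymmetric cases and makes this baseline fragile).

Two design points were genuinely open and resolved as follows:

* *Which principal axis seeds the plane?* All three axes are scored once by
  the mean nearest-neighbour distance between the mirrored and original
  cloud, and the best is kept. This removes an arbitrary failure mode: on
  elongated skulls the mirror normal is usually *not* the longest axis, and
  a wrong PCA pick is unrecoverable downstream.
* *How does the ICP rotation update the plane?* Composing the current
  reflection with the ICP rotation gives an orthogonal map with determinant
  −1, i.e. almost a reflection; its unit eigenvector at eigenvalue −1 is the
  mirror normal of the nearest reflection, and becomes the new plane normal.
  This is equivalent to rotating the normal by *half* the ICP rotation angle
  (applying the full rotation over-corrects and oscillates) and resolves the
  sign ambiguity of the half-angle rule deterministically.
* *Inner registration residual.* Classic point-to-point ICP under-corrects
  badly on smooth, densely sampled shells: correspondences slide
  tangentially and the outer loop stalls several degrees from the true
  plane (measured on a phantom: a 5° perturbation stalls near 3.3°
  regardless of resolution). The inner loop therefore minimizes
  point-to-plane residuals by default (target normals from local PCA over
  12 neighbours, small-angle linearized updates), which recovers the same
  5° perturbation to machine precision in two outer iterations.
  `icp_register(method = "point")` retains the classic behavior and is the
  default for general point-cloud registration, where its planted-transform
  guarantees hold exactly.

## Symmetry assessments

`assess_plane()` implements the split-mirror-assess protocol: split the
model by the plane (voxels classified by center, signed distance ≥ 0 on side
A), reflect side B across the plane, then score

* **HD** — Hausdorff distance (mm) between the surface points of A and of
  reflected B, $\max(\max_a \min_b \|a-b\|, \max_b \min_a \|a-b\|)$, with
  kd-tree nearest-neighbour queries. Surface points are face-exposed
  foreground voxel centers, or mesh vertices when a mesh is supplied.
* **JSC / DSC** — Jaccard and Dice overlap between the voxelized A and
  reflected B, the reflected centers re-binned onto the source grid by
  half-open containment (no antialiasing). The identity
  $\mathrm{DSC} = 2\,\mathrm{JSC}/(1+\mathrm{JSC})$ holds to $10^{-9}$ by
  construction; re-binning costs at most ~0.02 on symmetric fixtures.

Which side is reflected is immaterial (reflection is an isometry); side B is
used deterministically. `plane_angle()` reports the orientation-insensitive
3D angle $\arccos|n_1 \cdot n_2|$ in $[0°, 90°]$.

`compare_methods_wilcoxon()` compares methods over paired cases with
two-sided Wilcoxon signed-rank tests, one per method pair and assessment, at
$\alpha = 0.05$. For up to 25 informative pairs the p-value comes from the
exact sign-flip permutation distribution of the signed-rank statistic,
computed by dynamic programming over doubled ranks — this stays exact under
tied differences, where the classical exact algorithm refuses and a normal
approximation would be silently substituted. Raw p-values are reported (an
optional Holm adjustment is off by default, matching the usual reporting
convention for this three-way comparison).

## The phantom generator

No patient data ships with the package; every algorithm is exercised on
synthetic skull phantoms with exactly known ground truth.

`make_symmetric_phantom()` builds a hollow, egg-shaped vault: an ellipsoid
shell (default outer semi-axes $40 \times 52 \times 48$ mm, wall 3 mm,
voxels 1.5 mm) whose posterior semi-axis is shrunk to 0.82 b and inferior
semi-axis to 0.85 c, with two spherical orbit voids carved into the upper
face and a solid ellipsoidal jaw block attached below the front. The egg
shape matters: a plain ellipsoid shell is nearly mirror-symmetric
front-back and top-bottom as well, and those spurious planes can out-score a
resampling-degraded true plane (on a rotated plain-ellipsoid phantom a
spurious mirror reached SR 0.934 while the nearest-neighbour-resampled true
plane scored about 0.93; after the egg shaping the spurious mirrors score
≤ 0.69). A
real cranium has no such secondary mirrors, so the phantom should not
either.

The occupancy is computed for one half-grid and mirrored into the other by
an index flip, so the phantom is *exactly* symmetric about $x = 0$ and
$\mathrm{SR}(\text{truth plane}) = 1$ exactly. Synthetic landmarks (CG, ANS
on the midplane; OrR/OrL mirror-symmetric at the orbit floors) support the
landmark baseline.

Perturbations:

* `add_protrusion()` — a hollow spherical shell (wall 1 mm; radii 5–50 mm
  supported) attached at a fixed point on the jaw flank, emulating a
  unilateral tumor. The stored truth plane is deliberately *not* updated:
  robustness is measured against the pre-perturbation plane. The jaw block
  is sized so that a 30 mm sphere's shell clears it, keeping the voxelized
  shell volume within 10% of the analytic $4\pi r^2 t$ at 1 mm resolution.
* `apply_rigid()` — rotation (degrees, about the grid center) and
  translation; occupancy resampled nearest-neighbour, truth plane and
  landmarks transformed analytically, enabling parameter-recovery tests.
* `add_asymmetry()` — unilateral scaling of one half-space along the truth
  normal (hemifacial overgrowth stand-in), or Gaussian landmark jitter
  (operator variability); both reproducible from one integer seed.

What the phantoms do *not* emulate: CT noise, metal streak artifacts,
partial-volume effects at the bone-tissue boundary, and anatomical shape
detail. Passing tests therefore demonstrate correctness of the geometry and
optimization machinery under controlled asymmetry, not segmentation
robustness on clinical data.

## Numerical choices and problem sizes

* All physical quantities are mm; grids may be anisotropic. Voxel boxes are
  half-open (lower-inclusive); thresholding is inclusive (≥).
* Non-uniform slice stacks are resampled to a uniform z-grid by
  nearest-slice assignment (ties to the lower slice) — nearest-neighbour is
  the only interpolation that preserves binarity.
* The test and acceptance protocols run the study-scale phantom
  (~21k foreground voxels at 1.5 mm) for the symmetric fixed point and the
  protrusion suite, and a smaller phantom (semi-axes 20/26/24 mm) at 1 mm
  for pose recovery; these sizes keep a full run of the deterministic search
  (~250k SR evaluations per plane fit) to about a minute per fit while
  leaving the voxel count large enough that resampling noise stays below
  the tolerances being asserted.
* The paired-voxel kernel and the kd-tree (nearest and k-nearest queries)
  are C++; a hand-written kd-tree is used because the search is the
  package's hot path and must be dependency-free.
* Degenerate inputs fail loudly: empty grids, planes that do not bisect the
  model, collinear landmarks (with a distance diagnostic), rank-deficient
  point clouds, non-increasing slice positions.

## Known limitations

* The OSP search is exhaustive-then-local; with the default full-domain
  scan a fit costs minutes on large 1 mm clinical grids in a single thread.
  The `cone_deg` option restricts the orientation scan when the approximate
  head orientation is known, which is the common clinical case.
* Pairing is binary (no sub-voxel antialiasing), so OSR carries a
  resolution-dependent bias: rotated or resampled volumes lose a few
  percent of pairs at the true plane.
* The landmark baseline is only as good as the landmarks; the generator
  places them perfectly unless jitter is requested.
* DICOM series must be thresholded to masks upstream or supplied as
  NIfTI/NRRD/slice stacks; no DICOM parser is included.
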