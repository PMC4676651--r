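---
title: "Airway segmentation, centerlines and reference evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Airway segmentation, centerlines and reference evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airtree)
```

# The problem

Bronchoscopic planning and navigation need two things from a thoracic CT
before the procedure: a segmentation of the airway lumen and the centerline
tree of the bronchial branches, ideally produced automatically. Airway
segmentation is hard for a characteristic reason: the lumen (≈ −1000 HU)
and the surrounding lung parenchyma (≈ −850 HU) are both nearly air, and
they are separated only by a thin airway wall. Noise or partial-volume
holes in that wall let intensity-based region growing spill into the
parenchyma — *leakage* — while too-conservative settings lose the small
peripheral branches. This package implements a fully automatic pipeline
(tube filter → centerline → gradient-gated growing), the classic
threshold-interval growing as a comparator, the standard airway-tree
metrics, and the reference-evaluation formulas used to score candidate
segmentations against labelled ground truth. A synthetic phantom generator
supplies ground truth so that every stage is testable without patient data.

# The phantom: study conditions and what they emulate

`phantom_spec()` defines a dichotomous tree of straight capsules. The
defaults are the conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| trachea radius | 9 mm | adult trachea ≈ 18 mm diameter |
| radius taper | 0.7 / generation | gives ≈ 2.2 mm radius at generation 5, matching reported 2.8 ± 0.6 mm diameters of segmental bronchi at ≈ 4–5 mm diameter |
| trachea length | 30 mm, taper 0.7 | compact but keeps every branch longer than twice its parent's radius, as in real airways |
| branching angle | 35° per child | within the 25–45° range of reported bronchial branching half-angles |
| spacing | 0.5 mm isotropic | the slice increment of typical thin-slice thoracic CT |
| lumen / parenchyma / wall | −1000 / −850 / 0 HU | air, aerated parenchyma, soft-tissue wall |
| wall thickness | 1.5 mm | ≈ 15 % of local diameter for central airways, and ≥ 3 voxels so the wall is closed at the default spacing |
| noise | 0 or 20 HU (tests) | quiet reconstruction vs. typical clinical noise |

Children are rotated ±35° from the parent direction in planes that
alternate between generations, so the tree spreads in 3D as real bronchi
do. Ground-truth centerline points are sampled at most half a voxel apart;
reference labels mark the lumen *correct*, a one-voxel rind *unknown* (the
tolerance zone at the blurred lumen boundary), and everything else *wrong*.
The trachea and main-bronchus sub-masks are the generation-1 and
generation-2 lumen voxels, supporting the evaluation exclusions.

What the phantom does **not** emulate: parenchymal texture (vessels,
septa), cartilage rings, non-dichotomous branching, curved branches,
pathology (tumours, mucus plugs), and the partial-volume blur of a real
scanner point-spread function (walls here are sharp). Passing tests on
phantoms therefore demonstrate the geometric and topological correctness
of the algorithms and their noise tolerance, not clinical performance:
notably, the phantom's sharp 3-voxel walls make leakage *harder* than in a
real CT, which is why the leak tests punch an explicit wall hole.

One geometric property of the phantom matters for interpretation: with
radius 6.3 mm main bronchi diverging at 35°, the two lumina genuinely
overlap for ≈ 9 mm below the carina. The air space there is one cavity,
and a skeleton of it contains a transverse connection. The radius-adaptive
pruning described below removes it, and the same mechanism deals with real
near-carinal geometry.

# Tube probability

The filter is a Frangi-type vesselness on the sign-flipped Hessian (dark
tubes): per scale σ the volume is smoothed with a Gaussian of that width,
the Hessian is γ-normalised (γ = 2), and voxels with the tube-like
eigenvalue signature (two large negative eigenvalues after the flip)
score

$$V(\sigma) = \left(1-e^{-R_A^2/2\alpha^2}\right)\,e^{-R_B^2/2\beta^2}\,\left(1-e^{-S^2/2c^2}\right)$$

with α = β = 0.5 and c = `contrast_hu`/2 (default 75 HU, i.e. the
structureness term saturates at half the lumen–parenchyma contrast). The
map is the maximum over scales, rescaled to [0, 1]. Two numerical choices:

* **Scale set** {1.5, 2, 3, 4.5, 6} mm. The optimal Gaussian scale for a
  tube of radius r is ≈ 0.7 r, so 6 mm already captures a 9 mm-radius
  trachea; omitting larger scales keeps a usable interior margin on
  tightly cropped volumes (see next point).
* **Border validity.** Gaussian derivatives use reflect padding, and a
  mirror image of a bright wall just outside the border manufactures a
  dark valley *on* the border that scores as a tube. Each scale's response
  is therefore zeroed within one scale of the volume border. After
  `auto_crop()` (2-voxel pad) the airway always lies inside the valid
  region.

The map is invariant to adding a constant to the whole volume (only
second derivatives enter), which is asserted as a property test.

# Centerline extraction

Candidate voxels are those with probability ≥ 0.5 **and** intensity below
the air window `hu_air_max` (default −925 HU). The intensity condition is
load-bearing: curvature alone cannot distinguish the airway lumen from the
wedge-shaped channels of near-air parenchyma that run between two airway
walls below every bifurcation — both are dark elongated structures. The
only local feature separating them is absolute intensity (−1000 vs
−850 HU), the same reason airway parameter presets in practice include an
intensity window. Setting `hu_air_max = Inf` disables the window.

The largest 26-connected candidate component is then:

1. **Closed and filled** (one-voxel morphological closing, cavity fill).
   A threshold isosurface is bumpy; its small handles and enclosed pits
   are *topological* features that a topology-preserving thinning must
   keep, which would litter the skeleton with loops and shells. Closing
   seals them before thinning.
2. **Thinned** to a unit-width skeleton by sequential topology-preserving
   thinning with six directional sub-iterations; a voxel is deletable iff
   it is simple (one 26-connected foreground component among its 26
   neighbours and one 6-connected background component in its
   18-neighbourhood touching it) and not a curve endpoint. Candidates are
   scanned and deleted in raster order, making the result deterministic.
3. **Linked and rooted**: skeleton voxels become graph nodes with
   26-adjacency edges; incidental triangles are resolved by a BFS spanning
   tree from the root, the endpoint with the maximal z coordinate (the
   cranial end of the trachea).
4. **Pruned and trimmed.** Besides the fixed-length spur prune (default
   2 × mean spacing), three artifact classes intrinsic to thinning thick
   tubes are removed, each scaled by the *local tube radius* (distance
   from a point to the nearest background voxel, measured on the air mask
   when available because the thresholded response core is systematically
   slimmer than the lumen):
   * terminal branches whose straight-line chord is shorter than 1.7 ×
     the parent branch's tube radius (median inscribed radius over the
     parent's middle third, which avoids the inflated radii inside
     junction blobs) — these are the junction twigs and the "crow's feet"
     that thinning grows inside junction blobs and at blunt tube ends.
     Artifact chords stay below ≈ 1.5 × that radius; the shortest real
     branches in airway-like geometry sit near 1.9 ×, so 1.7 splits the
     two populations;
   * a short single-child root stub (the surviving crow's-foot leg at the
     cranial end), removed with re-rooting at its child;
   * terminal tails that run past the tube end into its rounded cap:
     each free tip is walked inward while the inscribed radius still
     increases (with half-a-voxel tolerance against discretisation
     jitter), so centerlines end at the centre of the last maximal
     inscribed sphere, which is the tube's axis endpoint.
5. **Smoothed** by two passes of a three-point moving average on interior
   points (junctions and endpoints fixed), removing the ≈ 2–5 % length
   inflation of voxel staircases.

Branches are maximal paths between junctions/terminals; the trachea is
generation 1 and each bifurcation increments the generation. A junction
with more than two children assigns all children the same next generation
rather than inventing short intermediate branches. On noise-free phantoms
of 1–5 generations both routes (probability map and mask thinning) recover
the branches-per-generation histogram exactly; this parameter-recovery
property is the package's main correctness check.

# Segmentation by gradient-gated growing

Seeds are all voxels within `dilation_radius_mm` (default 1 mm) of a
centerline point. Growth is 26-connected FIFO flood fill accepting voxels
that are (a) darker than `hu_ceiling` (default −500 HU) and (b) have local
gradient below `gradient_factor` × the wall gradient. Numerical choices:

* **Gradient measure**: the steepest one-sided difference over the 26
  neighbours, mm-scaled. Central differences are blind to a symmetric
  configuration — a one-voxel channel through a wall has walls on *both*
  sides of the throat voxel, so the central difference cancels exactly
  where the gate matters most; one-sided differences cannot be fooled this
  way.
* **Calibration**: the wall gradient is estimated per volume as the 95th
  percentile of the gradient measure over eligible voxels 26-adjacent to
  ineligible ones — by construction the air–tissue interface. Calibrating
  on the seed set's own boundary would measure homogeneous lumen
  (gradient ≈ 0 without noise) and shut the gate. `gradient_factor`
  defaults to 0.5: wall-adjacent voxels see the full wall gradient, hole
  throats see roughly 0.7–0.85 of it, interior voxels only noise.
* **Rind restoration**: the gate necessarily rejects the one-voxel lumen
  layer against the wall (it carries the wall gradient). A final
  conditional dilation adds eligible (below-ceiling) neighbours of
  growth-accepted voxels, restoring that rind without crossing the wall;
  with growth disabled (`gradient_factor = 0`) nothing is restored and the
  output is exactly the seed set.

On phantoms with a punched one-voxel wall hole, threshold-interval growing
at a parenchyma-inclusive range floods the lung, while the gated growth
stays inside the lumen — the comparative leakage property asserted in the
tests.

# Evaluation semantics

The formulas follow the reference-segmentation convention: *unknown*
voxels count nowhere; the trachea is excluded from every measure; the main
bronchi are additionally excluded from the correct/wrong voxel counts
behind the false-positive rate. Interpretations this package fixes where
the convention is silent:

* a reference branch is *detected* iff at least one candidate centerline
  point falls into a voxel carrying that branch's id (zero extra matching
  radius);
* detected tree length is measured along the *reference* centerline
  (segments with both endpoints in segmented voxels), so L_seg ≤ L_ref by
  construction;
* main bronchi are *included* in leakage counting (the exclusion is
  stated only for the false-positive rate);
* disconnected-but-correct segmented fragments count as detected;
* total centerline length counts only branches connected to the rooted
  tree.

Every formula is mirrored by an independent brute-force implementation in
the test suite (plain voxel/point loops), and both must agree exactly on
randomized corrupted segmentations of small phantoms.

# Problem sizes and determinism

The test suite runs phantoms of 1–5 generations (grids up to ≈ 240 × 230 ×
170 voxels at 0.5 mm) through the full pipeline, 10-seed self-evaluation
identities, and 50 randomized oracle comparisons on ≤ 32³ phantoms; the
whole suite completes in well under five minutes on one CPU, and the
acceptance script in under a minute. All stages are deterministic given
the configuration; the only randomness (phantom noise, leak-blob
placement) is seeded explicitly and restores the caller's RNG state.

# Known limitations

* The centerline spur heuristics assume airway-like proportions (branch
  length ≳ 2 × parent radius); degenerate trees with very short real
  branches would lose them.
* The air window in candidate selection presumes calibrated HU; data with
  large intensity offsets need `hu_air_max` adjusted (the tube-probability
  map itself is offset-invariant).
* The gradient gate stops leakage through narrow wall defects; a missing
  wall section wider than the smoothing scales looks like a genuine
  opening and will be entered.
* MetaImage support covers uncompressed MET_SHORT/MET_UCHAR/MET_FLOAT
  without direction cosines; DICOM, NIfTI and compressed MetaImage are out
  of scope.
* No anatomical labelling of branches; generations are purely topological.
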