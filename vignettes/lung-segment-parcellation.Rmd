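---
title: "Bronchopulmonary segment parcellation from airway centerlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bronchopulmonary segment parcellation from airway centerlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungparc)
```

## The problem and the model

The lungs divide into 5 lobes and, one level further down, into 18
bronchopulmonary segments, each ventilated by its own tertiary (segmental)
bronchus. Lobar boundaries follow visible fissures, but most segment
boundaries have no image contrast at all on CT: the practical definition of
a segment is *the lung tissue closest to its bronchus*. This package
implements that definition as a reusable toolkit:

1. **Taxonomy** — the fixed three-level anatomy (lungs, lobes, segments)
   with stable integer codes: right B1–B10 are 1–10, the eight left
   segments (B1/2, B3, B4, B5, B6, B7/8, B9, B10; two fused by convention)
   are 11–18, 0 is background.
2. **Probability maps** — the tracing target built from a centerline:
   rasterize the tree, take the Euclidean distance transform \(D(v)\) (mm,
   anisotropy-aware), and set \(p(v) = \exp(-D(v)^2 / 2\sigma^2)\), so the
   probability is 1 exactly on the centerline and decays monotonically with
   distance from the bronchus center.
3. **Tracing** — extract a rooted centerline tree from a probability map by
   geodesic fast marching plus iterative backtracking (the strategy of the
   Rivulet neuron tracer), with a strictly positive speed floor so that
   small gaps in the map do not disconnect the tree.
4. **Labeling** — tertiary bronchi sit at generation 3 of the airway tree
   (trachea = 0, main bronchi = 1); one annotated point per segmental
   bronchus propagates its label through the branch and every downstream
   sub-branch.
5. **Parcellation** — every lobe voxel \(v\) receives the label
   \(s(v) = \arg\min_k d_k(v)\), where \(d_k\) is the Euclidean distance to
   the labeled centerline of segment \(k\) and \(k\) ranges over the
   segments of \(v\)'s own lobe only. The lobe hierarchy caps the candidate
   set at five (the right lower lobe's five segments). Background stays
   background and labels never cross lobe boundaries.
6. **Evaluation** — per-segment Dice, 95th-percentile Hausdorff distance
   (HD95), average symmetric surface distance (ASSD), and the *inclusion
   rate*: the fraction of a segment's detected bronchial centerline points
   that the predicted mask covers with the correct label.

Everything is testable without patient data through a synthetic thoracic
phantom generator.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sigma` (probability map) | 1.0 | mm | Decay scale of the Gaussian weighting; 1 mm matches the voxel pitch of the phantoms, giving a tube of usable probability ≈ 2.5 mm around the centerline. Exposed because the functional form of the smoothing is a modeling choice, not a measurement. |
| `prob_threshold` | 0.05 | – | Foreground gate of the tracer. At `sigma` = 1 mm this corresponds to ≈ 2.45 mm from the axis. |
| `speed_floor` | 1e-4 | – | Minimum marching speed; keeps every voxel reachable so that a locally zeroed map (a failed prediction) costs time instead of connectivity. |
| `coverage_fraction` | 0.98 | – | Stop when this fraction of foreground lies within the erasure radius of the traced tree. |
| `coverage_radius_mm` | 2.0 | mm | Floor of the erasure radius and the attachment radius for linking a path into the tree. |
| `step_mm` | half min spacing | mm | Backtracking step; sub-voxel so that descent can follow the interpolated time field. |
| `min_branch_nodes` | 3 | nodes | Paths contributing fewer *new* nodes are discarded as noise. |
| `out_spacing` (crop) | 2.0 | mm | Isotropic resampling pitch of the landmark-driven region of interest. |
| `margin_mm` (crop) | 150/100/150 | mm | Per-axis margins around the carina–sternum box; generous defaults meant to encompass both lungs, configurable because no canonical value exists. |

## The synthetic phantom

`generate_phantom()` builds, deterministically from one seed: two
ellipsoidal lungs (default 96³ voxels at 1 mm); a trachea descending to the
carina; one main bronchus per lung; 3 + 2 lobar branches steered towards
per-lobe anchor regions; segmental children with the anatomical 3/2/5/4/4
counts per lobe; and one sub-segmental generation (two children each).
Lobes are defined by nearest-lobar-subtree assignment inside each lung —
the same argmin machinery as the segment parcellation, one level up.
Ground-truth segment masks come from an *exhaustive* voxel-by-point scan
written independently of the production distance-transform path, so the two
implementations genuinely cross-check each other.

Two generator details keep the bundle self-consistent for any seed. Each
branch is redrawn (up to 50 jitter draws, bending towards the lung center
and shortening under repeated failure) until it stays inside the lung and
at least 2.5 mm clear of other lobes' and other segments' subtrees — closer
approaches could put two labels into one voxel and break the
inclusion-rate-equals-one identity that links the parcellation to the
metrics. If a sampled geometry still violates a bundle invariant, the whole
tree is redrawn from a derived seed; both loops are deterministic, so equal
specs give bit-identical bundles.

What the phantom does *not* emulate: CT intensities and noise (only masks,
centerlines and probability maps are produced), fissure-shaped lobe
boundaries, anatomically curved bronchi (branches are straight chains), and
anatomical variants such as accessory segments. Passing tests therefore
demonstrate the geometric and algorithmic correctness of the pipeline —
not performance on clinical CT, which additionally depends on the quality
of the probability-map predictor and the lobe segmentation that this
package takes as inputs.

## Numerical conventions

* **Distances** are measured in mm between voxel centers, with anisotropic
  spacing honored everywhere. The Euclidean distance transform is the exact
  separable lower-envelope algorithm (with nearest-site propagation), not a
  chamfer approximation; the test suite compares it against an all-pairs
  oracle.
* **Parcellation distance** \(d_k(v)\) is taken to the *rasterized* labeled
  centerline: the propagated nodes plus dense samples along labeled edges
  (at most half the minimum spacing apart), each mapped to its voxel
  center. Measuring to voxel centers (rather than continuous point
  positions) is what makes the fast distance-transform implementation agree
  with the exhaustive oracle voxel for voxel; the discretization it
  introduces is bounded by half a voxel diagonal. Ties break towards the
  smallest segment code, in both implementations.
* **Whole-subtree distance**: \(d_k\) uses every propagated point of
  segment *k* (tertiary branch plus downstream sub-branches), not only the
  clicked point — label propagation makes the entire subtree the bronchus.
* **Generations** count the trachea as 0, so main bronchi are generation 1
  and segmental candidates generation 3; trifurcations are allowed and each
  child branch is one generation deeper.
* **Eikonal solver**: first-order upwind (Godunov) fast marching on the
  voxel lattice with a binary heap; arrival times scale exactly inversely
  with a global speed scaling, and constant-speed times are within 5% of
  straight-line distance on the default grids.
* **HD95** uses the common linear-interpolation percentile convention
  (R's `quantile(..., type = 7)`) over the pooled symmetric surface-distance
  multiset; surfaces are 6-connectivity face boundaries, with volume-border
  voxels counting as surface. ASSD is the mean of the same multiset.
* **Aggregates** use the sample (n−1) standard deviation over the segments
  defined in both masks; missing segments are flagged and excluded.
* **Inclusion rate** denominators: the primary rate counts labeled
  centerline points that land on non-background predicted voxels, so gross
  lung under-segmentation surfaces as a separate signal instead of silently
  deflating the rate; the all-points variant is reported alongside it in
  the JSON.

## Tracer design

The published description of iterative backtracking leaves several details
open; this implementation fixes them as follows, with every constant
exposed in `tracer_params()`:

* **Origins** are foreground voxels whose arrival time is a local maximum
  within their foreground 26-neighborhood — geodesic endpoints, the
  farthest-point choice. Tube-fringe and junction-pocket voxels always
  have a foreground neighbor with larger time further downstream, and
  descending from them produces duplicate twigs rather than branches.
* **Descent** follows the negative gradient of the interpolated time field
  in `step_mm` steps (central differences, trilinear interpolation), with
  each step nudged half a step towards the probability ridge so the path
  stays on the tube axis. If the gradient stalls, the walker hops to the
  lowest-time voxel in its 26-neighborhood; a path that fails to make
  progress, or exceeds ten times its straight-line time budget, is
  discarded and its surroundings marked covered.
* **Termination of a path**: touching an existing tree node (within one
  step) or the seed. Stopping on nodes rather than on covered territory
  means proximal branch pieces are actually traversed instead of being
  bridged by long connection edges.
* **Erasure** after each path (kept or discarded) marks foreground within
  `max(coverage_radius_mm, local radius estimate)` of the path as covered,
  so a traced centerline retires its entire tube cross-section; kept paths
  additionally widen the erasure by 1 mm around their attachment end,
  where diverging tubes leave wedge-shaped pockets. The loop ends at
  `coverage_fraction` or when no uncovered endpoint remains; because every
  iteration covers at least its origin, it always terminates.
* **Radii** are estimated from the distance transform of the thresholded
  foreground at each node.

**Counting bifurcations.** A trifurcation (the right lung's three lobar
bronchi, or a lobar branch fanning into up to five segmental children) is
necessarily resolved by any sequential tracer as several binary
attachments a few millimetres apart. Branch counts are therefore compared
as anatomical branching *sites*: branch points merged by single linkage
within 3 mm (`count_branch_points(tree, merge_radius_mm = 3)`). The
phantom's own sites are isolated nodes, so its count (26 with the default
anatomy) is unchanged by the merge.

## Problem sizes used by the tests

The acceptance suite runs entirely on synthetic data: ten default 96³
phantoms for the candidate-bound property; twenty random 32³–64³ two-lobe
phantoms for the oracle-equivalence check; three phantoms for the
self-consistency metrics, the tracer recovery/branch-site comparison (as
averages over the three) and the reproducibility check; single small grids
for the closed-form metric and probability-map identities. On these sizes,
measured across dozens of seeds, the tracer recovers 96–99.5% of
centerline length within 1.5 mm and the three-phantom mean branching-site
count stays within ±10% of the truth.

## Known limitations

* Only axis-aligned volumes are supported: NIfTI affines must be diagonal
  up to axis flips, and oblique acquisitions are rejected rather than
  resampled.
* The tracer assumes tubes a few voxels wide (the regime of the default
  probability maps); very thin (sub-voxel) or very fat structures would
  need retuned `coverage_radius_mm` and `prob_threshold`.
* Branch generation numbering is advisory on traced trees: a missed
  segmental bronchus shifts everything below it, which is why annotations
  on a non-generation-3 branch warn instead of fail.
* The phantom's lobes are nearest-subtree territories, not fissure
  surfaces; segment shapes are therefore more convex than clinical ones.
* `crop_resample` uses two landmarks supplied by the caller (carina and
  sternum tips); landmark detection itself is out of scope, as are the
  CNNs that would predict probability maps and lobe masks from CT.
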