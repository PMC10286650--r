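---
title: "Template-based pancreas subsegmentation: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based pancreas subsegmentation: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative MRI of the pancreas (fat fraction, T1, volume) is usually
reported for the whole organ, but pancreatic disease — fatty infiltration,
fibro-inflammation, cancer — is spatially heterogeneous, and the three
anatomical segments (head, body, tail) behave differently. Given a
whole-pancreas binary segmentation, `pancparts` splits it into head, body
and tail fully automatically, so that downstream biomarkers can be
quantified per segment.

The approach is atlas-based. Offline, a cohort of whole-organ masks is
co-registered into a probabilistic shape template by groupwise
diffeomorphic registration; the template is binarized and annotated *once*
with two boundary planes (head–body and body–tail). At inference, a new
subject's mask is registered to the template, the annotated parts template
is carried back through the inverse warp, and the labels are propagated to
every foreground voxel of the subject. A spatial k-means clustering of
foreground voxel coordinates (k = 3, k-means++ seeding) is included as the
unsupervised baseline, and a metric suite (Dice, 95th-percentile Hausdorff
distance, volume deltas, Bland–Altman limits of agreement) plus a
PDFF-slice intersection module support validation and application.

## Registration model

The registration engine is a stationary-velocity diffeomorphic demons
scheme, chosen because every downstream consumer needs only two properties
of the warp: invertibility (labels travel backwards through the inverse)
and overlap improvement. Binary masks are smoothed with a Gaussian of
$\sigma = 1$ voxel and matched by mean squared difference. The velocity
field $v$ is updated with the classic demons force computed on the warped
moving image,
$$ d = \frac{(F - M_w)\,\nabla M_w}{\lVert\nabla M_w\rVert^2 + (F - M_w)^2},$$
fluid-smoothed ($\sigma = 1$ voxel), added to $v$, and the sum
elastic-smoothed ($\sigma = 1$ voxel). The warp is the group exponential
$\exp(v)$ computed by scaling-and-squaring (4 squarings), and the inverse
is $\exp(-v)$, which is exact for stationary fields — this is what
guarantees the forward∘inverse round trip stays below a voxel. The update
magnitude is intrinsically capped at half a voxel per iteration by the
demons normalization, and the Jacobians of $\exp(v)$ stay positive for the
smooth velocity fields the scheme produces; both properties are verified by
tests rather than assumed.

Multi-resolution runs coarse-to-fine at factors 4, 2, 1 with at most
60/40/20 iterations and stops a level after five consecutive iterations
with a relative similarity change below $10^{-5}$. Because a mask pair
occupies a fraction of the grid, the iterations run on the union foreground
bounding box plus an 8-voxel margin; outside it the transform is exactly
the identity. If the final warp fails to improve the Dice overlap the
identity transform is returned with a flag — the contract "never worse
than no registration" is enforced, not hoped for.

Two schedules are exposed: the full three-level schedule for inference, and
a two-level schedule (`reg_config_groupwise()`) that stops at half
resolution for template construction, where only approximate
correspondence is needed because the average is re-estimated every
iteration and binarized at the end.

## Groupwise template construction

The initial average is the voxelwise mean of the centroid-aligned masks.
Each of the (default four) groupwise iterations registers every mask to
the current average and replaces the average with the mean of the warped
masks. Two refinements matter:

* **Velocity centering.** After registering all subjects, the pointwise
  mean velocity is subtracted from each subject's velocity before warping.
  Without this, the average drifts: a small shape facing a large average
  keeps inflating until the template converges to the union of shapes.
  Centering makes the mean deformation the identity, so the template is an
  unbiased (Fréchet-mean-like) average — on two concentric spheres it
  lands strictly between them instead of collapsing to the larger one.
* **Warm starts.** From the second groupwise iteration on, each subject's
  registration is initialized from its previous velocity and run with a
  short polish schedule (a third of the iteration budget). This is an
  optimizer detail — every mask is still registered to the current
  average each iteration — but it cuts template construction time roughly
  threefold.

On identical inputs every velocity is exactly zero, so the template equals
the common mask: the fixed-point property is exact, not approximate.

Binarization uses an inclusive threshold (foreground where the template
value is $\ge$ 0.5) so behavior at ties is deterministic.

## Template annotation

Annotation is numeric: two oriented planes whose normals point from head
toward tail. Head voxels lie on the negative side of the head–body plane,
tail voxels on the positive side of the body–tail plane, body in between;
overlapping head and tail regions or an empty part raise errors rather
than silently relabeling. `annotate_by_arclength()` places both planes
orthogonal to the template's centerline: the head–body plane at a fixed
arc-length fraction (default 0.40) and the body–tail plane at the midpoint
between the head–body boundary and the tail tip — the conventional
anatomical definition of the body–tail boundary as the lengthwise midpoint
of the combined body and tail, which `midpoint_body_tail_boundary()`
implements as $s_{hb} + (L - s_{hb})/2$.

The centerline is the depth-weighted geodesic between the mask's two
geodesic extremities: a Dijkstra shortest path over the 26-connected
foreground graph with edge costs divided by the squared distance-to-
boundary, which pulls the path onto the medial axis. The extremities lie
*on the organ surface* at the tips, so each end of the path is trimmed
while the depth profile still climbs at a slope above 0.35 per mm of path
— the surface-to-axis climb has slope near 1, an anatomical taper near
0.15 — leaving a polyline that runs between the end-cap centers, on the
axis of a straight cylinder to within a voxel. A moving average (window 5)
smooths voxel quantization. The head end is identified as the bulkier end
(greater mean depth over the first quarter of the path), overridable with
an explicit orientation vector, and near-spherical shapes (extremity
geodesic distance less than 1.5 times the maximal inscribed diameter) are
rejected as degenerate. A skeletonization-based centerline would serve
equally; the geodesic formulation was chosen because it needs no 3D
thinning primitive and its two sweeps + one path are cheap and exactly
reproducible.

## Inference and label propagation

A new subject (already resampled to the template grid) is centroid-aligned
to the template by an integer-voxel shift, registered to the binarized
template, and the parts template is warped back through the inverse with
nearest-label interpolation, which can never invent label values. Subject
foreground voxels not covered by a warped label — typically a thin rind
where the subject is locally larger than the warped template — take the
label of the nearest labeled voxel in world mm (an exact anisotropic
Euclidean distance transform per label; ties go to the lowest label, i.e.
head before body before tail). The result therefore partitions the subject
mask exactly, by construction, and the fraction of directly covered
foreground is reported as `warped_parts_coverage`.

## The k-means baseline

The baseline clusters foreground voxel world coordinates only — the input
is a binary mask, so there are no intensities or motion features — with
k = 3, k-means++ seeding under a caller-supplied seed (authored here
because the stock Lloyd implementation does not provide it), and Lloyd
iterations delegated to `stats::kmeans` (at most 300). Clusters become
head/body/tail by ascending centroid projection onto the head-to-tail
axis; the automatic axis is the first principal component, signed so the
bulkier end (larger perpendicular spread over the lowest projection
quartile) is the head. On a uniform straight tube the optimal 3-means
splits into equal thirds; the tests verify the boundaries against an exact
1-D dynamic-programming oracle rather than against an approximation.

## Metrics

Dice is $2|A\cap B|/(|A|+|B|)$, with the both-empty case defined as 1
(agreement on absence) under a warning. The 95 % Hausdorff distance uses
boundary voxels from a 6-connectivity erosion difference, exact
anisotropic Euclidean distances in mm, the *pooled* symmetric set of both
directed nearest-distance sets, and linear interpolation between order
statistics for the percentile; all three conventions (boundary
definition, pooling, percentile rule) are choices this package documents
and tests against a brute-force all-pairs oracle to $10^{-9}$. Volumes are
foreground count times the voxel volume ($|\det|$ of the affine's linear
part). Bland–Altman limits of agreement are bias $\pm$ 1.96 sample
standard deviations (n−1) of the paired differences. Wilcoxon signed-rank
and Mann–Whitney tests pass through to `stats::wilcox.test`.

## PDFF intersection and quality control

A 2D PDFF slice carries its own scanner-coordinate geometry (from NIfTI,
or built from the DICOM ImagePositionPatient / ImageOrientationPatient /
PixelSpacing fields with LPS→RAS conversion). Each pixel center is mapped
to world coordinates and into the 3D label volume with the nearest-label
rule; slice thickness is deliberately ignored (plane sampling, not slab
averaging). Per part, QC runs in a fixed order: (1) raw resliced area of
$\le 30$ pixels excludes the part (`small_segment`; parts absent from the
slice are `not_in_slice`); (2) pixels strictly above 50 % PDFF — at
exactly 50.0 % they are retained — or missing are removed; (3) the
surviving mask is opened with the discrete disk of 3-pixel diameter (the
3×3 cross); (4) a part emptied by the opening is `emptied_by_qc`,
otherwise the median over the opened mask is reported (even counts: mean
of the two central order statistics). The area test is applied once, on
the raw mask, not re-applied after opening — the emptied case is its own
explicit outcome. The whole-pancreas value merges all part labels first
and then runs the identical procedure, so a whole pancreas can be
reportable even when every individual part is too small on its own.

## The phantom generator

Real pancreas segmentations are access-controlled, so validation runs on a
synthetic cohort whose ground truth is known by construction. A phantom is
a curved tube: a natural cubic spline through 5 control points, densely
resampled (1000 samples), with a radius profile interpolating head → body
→ tail radii along arc length; a voxel is foreground iff it lies within
the local radius of the nearest centerline sample. Ground-truth labels are
assigned by nearest-sample arc length — head below 0.40 of the length,
body–tail boundary at the midpoint of the remainder — so the truth is
exact even on curved tubes, without any plane approximation. Defaults
(85 mm centerline, 12 mm bowing, radii 10.5/8/5.5 mm tapering head to
tail, 2 mm isotropic 64³ grid) are a pancreas-like shape scaled to fit the
desk-scale grid; cohorts draw uniform ±15 % radius jitter and Gaussian
1.5 mm control-point perturbations per subject, all reproducible from a
single seed.

What the phantom does *not* emulate: lobulated or notched organ surfaces,
the duodenal C-loop context, segmentation errors in the input masks,
multi-component or touching-organ artifacts, and any intensity content.
Passing phantom tests therefore demonstrates the pipeline's geometric
correctness (partitioning, invertibility, boundary placement on smooth
elongated shapes), not robustness to real segmentation noise.

## Problem sizes and numerical choices

The validation suite uses 64³ grids at 2 mm spacing, a 20-phantom
leave-one-out for parameter recovery (each fold builds its own template
from the other 19 with 4 groupwise iterations and subsegments the held-out
subject), 50 phantoms for the partition property, 10 pairs for the
registration contract, and 20 random 16³ pairs for the metric oracles —
sizes chosen so the full suite runs on a single CPU in well under half an
hour while still exercising every stage end to end.

Other fixed numerical choices: masks read from disk threshold at > 0.5
(tolerates 0/255 and interpolated encodings); mask resampling is linear
interpolation + 0.5 threshold, label resampling nearest-label, and the
joint mask+label resampler repairs any disagreement with a nearest-label
fill so the partition property survives resampling; centroid alignment
uses integer-voxel shifts (masks stay exactly binary; the sub-voxel
residual, at most half a voxel per axis, is absorbed by registration);
probabilistic templates are stored as 32-bit floats and label maps as
unsigned 8-bit.

## Known limitations

* The demons engine assumes the two shapes are roughly pre-aligned
  (centroid alignment is built into the pipeline); it performs no rigid
  rotation search, matching the translation-only pre-alignment design.
* Displacement fields are expressed along the grid axes in mm; for oblique
  affines the "world" offsets are grid-aligned, which is consistent for
  the within-pipeline use (all volumes share the grid) but would need a
  rotation for an external consumer with a different frame.
* The Hausdorff implementation assumes orthogonal voxel axes when
  converting to mm (true for all grids this pipeline produces).
* The head/tail orientation heuristics (bulkier end) assume the organ's
  head is thicker than its tail, which holds for the pancreas and the
  phantom family; for other organs supply an explicit orientation vector.
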